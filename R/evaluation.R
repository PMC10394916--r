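#' Restrict predictions to the gold-standard node universe
#'
#' Predicted complexes are compared with known complexes only over the
#' proteins the gold standard knows about: each predicted set is intersected
#' with the union of all known complex members, and sets falling below
#' `min_size` afterwards are dropped.
#'
#' @param predicted list of character vectors (predicted complexes).
#' @param known a [complex_collection].
#' @param min_size size floor after filtering (default 3).
#' @return filtered list of character vectors.
#' @export
filter_to_known_nodes <- function(predicted, known, min_size = 3) {
  universe <- unique(unlist(known$members, use.names = FALSE))
  out <- lapply(predicted, intersect, y = universe)
  out[lengths(out) >= min_size]
}

#' F-similarity between a predicted and a known complex
#'
#' Harmonic mean of the two intersection ratios
#' p' = |Cp ∩ Ck| / |Cp| and r' = |Cp ∩ Ck| / |Ck|; 0 when the complexes
#' are disjoint.
#'
#' @param cp,ck nonempty character vectors.
#' @return F-similarity in [0, 1].
#' @export
f_similarity <- function(cp, ck) {
  if (length(cp) == 0 || length(ck) == 0) stop("complexes must be nonempty")
  ov <- length(intersect(cp, ck))
  if (ov == 0) return(0)
  p <- ov / length(cp)
  r <- ov / length(ck)
  2 * p * r / (p + r)
}

harmonic2 <- function(a, b) if (a + b == 0) 0 else 2 * a * b / (a + b)

as_member_list <- function(x) {
  if (inherits(x, "complex_collection")) x$members else x
}

f_similarity_matrix <- function(predicted, known) {
  outer(seq_along(predicted), seq_along(known),
        Vectorize(function(i, j) f_similarity(predicted[[i]], known[[j]])))
}

# Maximum-weight bipartite matching weight of a nonnegative matrix
# (rows = predicted, cols = known), via igraph's weighted matcher.
max_matching_weight <- function(W) {
  keep <- which(W > 0, arr.ind = TRUE)
  if (nrow(keep) == 0) return(0)
  nr <- nrow(W); nc <- ncol(W)
  edges <- rbind(keep[, 1], nr + keep[, 2])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nr), rep(TRUE, nc)),
                                    as.vector(edges))
  m <- igraph::max_bipartite_match(g, weights = W[keep])
  m$matching_weight
}

#' Maximal-matching F-score (FMMF)
#'
#' Builds the complete bipartite graph between predicted and known
#' complexes with F-similarities as edge weights and computes the weight W
#' of a maximum-weight matching. The adapted maximal matching ratio
#' (recall) is W divided by the number of known complexes, precision is W
#' divided by the number of predicted complexes, and the FMMF is their
#' harmonic mean.
#'
#' @param predicted nonempty list of character vectors (or a
#'   [complex_collection]).
#' @param known nonempty [complex_collection] (or list of character
#'   vectors).
#' @return named numeric vector `c(precision, recall, fscore)`.
#' @export
fmmf <- function(predicted, known) {
  predicted <- as_member_list(predicted)
  known <- as_member_list(known)
  if (length(predicted) == 0 || length(known) == 0) {
    stop("both collections must be nonempty")
  }
  W <- max_matching_weight(f_similarity_matrix(predicted, known))
  precision <- W / length(predicted)
  recall <- W / length(known)
  c(precision = precision, recall = recall,
    fscore = harmonic2(precision, recall))
}

#' Community-wise maximum F-similarity F-score (CMMF)
#'
#' Recall side: mean over known complexes of the best F-similarity to any
#' predicted complex. Precision side: mean over predicted complexes of the
#' best F-similarity to any known complex. CMMF is their harmonic mean.
#'
#' @inheritParams fmmf
#' @export
cmmf <- function(predicted, known) {
  predicted <- as_member_list(predicted)
  known <- as_member_list(known)
  if (length(predicted) == 0 || length(known) == 0) {
    stop("both collections must be nonempty")
  }
  S <- f_similarity_matrix(predicted, known)
  precision <- mean(apply(S, 1, max))
  recall <- mean(apply(S, 2, max))
  harmonic2(precision, recall)
}

#' Sn-PPV accuracy (SPA) and its unbiased variant (UnSPA)
#'
#' Based on the overlap-count matrix `T[i, j] = |known_i ∩ predicted_j|`:
#' sensitivity `Sn = sum_i max_j T_ij / sum_i |known_i|`, positive
#' predictive value `PPV = sum_j max_i T_ij / sum_j sum_i T_ij`, and
#' `SPA = sqrt(Sn * PPV)`. The unbiased variant replaces the size-weighted
#' sums by per-complex means: `Sn_u = mean_i(max_j T_ij / |known_i|)`,
#' `PPV_u = mean_j(max_i T_ij / |predicted_j|)`,
#' `UnSPA = sqrt(Sn_u * PPV_u)`.
#'
#' @inheritParams fmmf
#' @return named numeric vector `c(spa, unspa)`.
#' @export
spa_unspa <- function(predicted, known) {
  predicted <- as_member_list(predicted)
  known <- as_member_list(known)
  if (length(predicted) == 0 || length(known) == 0) {
    stop("both collections must be nonempty")
  }
  T_ <- outer(seq_along(known), seq_along(predicted),
              Vectorize(function(i, j) {
                length(intersect(known[[i]], predicted[[j]]))
              }))
  sn <- sum(apply(T_, 1, max)) / sum(lengths(known))
  tot <- sum(T_)
  ppv <- if (tot == 0) 0 else sum(apply(T_, 2, max)) / tot
  sn_u <- mean(apply(T_, 1, max) / lengths(known))
  ppv_u <- mean(apply(T_, 2, max) / lengths(predicted))
  c(spa = sqrt(sn * ppv), unspa = sqrt(sn_u * ppv_u))
}

#' Qi et al. F-score
#'
#' A predicted/known pair "matches" when both intersection ratios exceed
#' `tau` strictly. Precision is the fraction of predicted complexes with at
#' least one match, recall the fraction of known complexes with at least
#' one match; the score is their harmonic mean.
#'
#' @inheritParams fmmf
#' @param tau match threshold on both intersection ratios (default 0.25).
#' @export
qi_fscore <- function(predicted, known, tau = 0.25) {
  predicted <- as_member_list(predicted)
  known <- as_member_list(known)
  if (length(predicted) == 0 || length(known) == 0) {
    stop("both collections must be nonempty")
  }
  M <- outer(seq_along(predicted), seq_along(known),
             Vectorize(function(i, j) {
               ov <- length(intersect(predicted[[i]], known[[j]]))
               ov / length(predicted[[i]]) > tau &&
                 ov / length(known[[j]]) > tau
             }))
  precision <- mean(apply(M, 1, any))
  recall <- mean(apply(M, 2, any))
  harmonic2(precision, recall)
}

k_subsets <- function(members, k) {
  if (length(members) < k) return(character(0))
  apply(utils::combn(sort(members), k), 2, paste, collapse = "\r")
}

#' k-clique F-scores
#'
#' Decomposes every complex into its k-member subsets ("k-cliques") for
#' k = 2..`k_max` and compares the predicted and known k-set collections:
#' `precision_k` is the fraction of predicted k-sets that are also known
#' k-sets, `recall_k` the converse, `F_k` their harmonic mean; k levels
#' with no sets on either side are skipped. `f_grand` is the unweighted
#' mean of the `F_k`, `f_weighted` the mean weighted by the number of known
#' k-sets. Complexes larger than `size_cap` are excluded from enumeration
#' with a warning (combinatorial guard).
#'
#' @inheritParams fmmf
#' @param k_max largest subset size enumerated (default 10).
#' @param size_cap complexes larger than this are skipped (default 20).
#' @return named numeric vector `c(f_grand, f_weighted)`.
#' @export
kclique_fscores <- function(predicted, known, k_max = 10L, size_cap = 20L) {
  predicted <- as_member_list(predicted)
  known <- as_member_list(known)
  if (length(predicted) == 0 || length(known) == 0) {
    stop("both collections must be nonempty")
  }
  guard <- function(sets, side) {
    big <- lengths(sets) > size_cap
    if (any(big)) {
      warning(sprintf("excluding %d %s complex(es) larger than %d from %s",
                      sum(big), side, size_cap, "k-set enumeration"))
    }
    sets[!big]
  }
  predicted <- guard(predicted, "predicted")
  known <- guard(known, "known")
  f_k <- numeric(0)
  n_known_k <- numeric(0)
  for (k in 2:k_max) {
    pk <- unique(unlist(lapply(predicted, k_subsets, k = k),
                        use.names = FALSE))
    kk <- unique(unlist(lapply(known, k_subsets, k = k),
                        use.names = FALSE))
    if (length(pk) == 0 && length(kk) == 0) next
    ov <- length(intersect(pk, kk))
    precision <- if (length(pk) == 0) 0 else ov / length(pk)
    recall <- if (length(kk) == 0) 0 else ov / length(kk)
    f_k <- c(f_k, harmonic2(precision, recall))
    n_known_k <- c(n_known_k, length(kk))
  }
  if (length(f_k) == 0) return(c(f_grand = 0, f_weighted = 0))
  f_weighted <- if (sum(n_known_k) == 0) 0 else
    sum(f_k * n_known_k) / sum(n_known_k)
  c(f_grand = mean(f_k), f_weighted = f_weighted)
}

#' Full evaluation report
#'
#' Applies [filter_to_known_nodes()] and computes every metric of the
#' suite. If every prediction is filtered away the report is all zeros,
#' with a warning.
#'
#' @inheritParams fmmf
#' @param min_size size floor applied after node filtering (default 3).
#' @param qi_tau Qi et al. match threshold (default 0.25).
#' @param k_max,size_cap see [kclique_fscores()].
#' @return data.frame of class `evaluation_report` with one row and columns
#'   `fmm_precision`, `fmm_recall`, `fmm_fscore`, `cmmf`, `unspa`, `spa`,
#'   `qi_f1`, `f_grand_kclique`, `f_weighted_kclique`.
#' @export
evaluate_all <- function(predicted, known, min_size = 3, qi_tau = 0.25,
                         k_max = 10L, size_cap = 20L) {
  predicted <- as_member_list(predicted)
  pred <- filter_to_known_nodes(predicted, known, min_size = min_size)
  zero <- data.frame(fmm_precision = 0, fmm_recall = 0, fmm_fscore = 0,
                     cmmf = 0, unspa = 0, spa = 0, qi_f1 = 0,
                     f_grand_kclique = 0, f_weighted_kclique = 0)
  if (length(pred) == 0) {
    warning("all predictions filtered away; returning zero report")
    class(zero) <- c("evaluation_report", class(zero))
    return(zero)
  }
  fm <- fmmf(pred, known)
  sp <- spa_unspa(pred, known)
  kc <- kclique_fscores(pred, known, k_max = k_max, size_cap = size_cap)
  out <- data.frame(fmm_precision = unname(fm["precision"]),
                    fmm_recall = unname(fm["recall"]),
                    fmm_fscore = unname(fm["fscore"]),
                    cmmf = cmmf(pred, known),
                    unspa = unname(sp["unspa"]),
                    spa = unname(sp["spa"]),
                    qi_f1 = qi_fscore(pred, known, tau = qi_tau),
                    f_grand_kclique = unname(kc["f_grand"]),
                    f_weighted_kclique = unname(kc["f_weighted"]))
  class(out) <- c("evaluation_report", class(out))
  out
}
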