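#' Qi overlap criterion between two complexes
#'
#' Two complexes overlap in the Qi sense at threshold t when both
#' intersection ratios exceed t strictly:
#' `|Cp ∩ Ck| / |Cp| > t` and `|Cp ∩ Ck| / |Ck| > t`.
#'
#' @param cp,ck nonempty character vectors (complexes).
#' @param t overlap threshold in (0, 1).
#' @return logical.
#' @export
qi_overlap <- function(cp, ck, t) {
  if (length(cp) == 0 || length(ck) == 0) stop("complexes must be nonempty")
  stopifnot(t > 0, t < 1)
  ov <- length(intersect(cp, ck))
  (ov / length(cp) > t) && (ov / length(ck) > t)
}

cand_key <- function(members) paste(members, collapse = "\r")

#' Merge highly overlapping candidate complexes
#'
#' Repeatedly takes the currently best-scoring pair of candidates that
#' satisfies the Qi overlap criterion at threshold `t`, forms their union
#' (scored by a value-table lookup at the union's density bin), and
#' replaces the pair by the single highest-scoring variant among the two
#' originals and the union (ties prefer the union, then the larger member
#' set, then the lexicographically smaller one). Each step removes one
#' candidate, so the procedure terminates with no qualifying pair left.
#'
#' @param candidates list of `candidate_complex` objects (deduplicated,
#'   e.g. from [predict_all()]).
#' @param t Qi overlap threshold.
#' @param table a [value_table] (scores union candidates).
#' @param network a [ppi_network].
#' @return merged list of candidates, sorted by score descending then
#'   members lexicographically.
#' @export
merge_candidates <- function(candidates, t, table, network) {
  if (length(candidates) <= 1) return(candidates)
  # drop duplicates defensively
  key <- vapply(candidates, function(cc) cand_key(cc$members), "")
  candidates <- candidates[!duplicated(key)]
  repeat {
    n <- length(candidates)
    if (n < 2) break
    scores <- vapply(candidates, `[[`, 0, "score")
    keys <- vapply(candidates, function(cc) cand_key(cc$members), "")
    best_pair <- NULL
    best_rank <- NULL
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (!qi_overlap(candidates[[i]]$members,
                        candidates[[j]]$members, t)) next
        hi <- max(scores[i], scores[j]); lo <- min(scores[i], scores[j])
        ka <- min(keys[i], keys[j]); kb <- max(keys[i], keys[j])
        rank <- list(hi = hi, lo = lo, ka = ka, kb = kb)
        better <- is.null(best_rank) ||
          rank$hi > best_rank$hi ||
          (rank$hi == best_rank$hi && rank$lo > best_rank$lo) ||
          (rank$hi == best_rank$hi && rank$lo == best_rank$lo &&
             (rank$ka < best_rank$ka ||
                (rank$ka == best_rank$ka && rank$kb < best_rank$kb)))
        if (better) {
          best_rank <- rank
          best_pair <- c(i, j)
        }
      }
    }
    if (is.null(best_pair)) break
    a <- candidates[[best_pair[1]]]
    b <- candidates[[best_pair[2]]]
    u_members <- sort(union(a$members, b$members))
    u_state <- density_state(u_members, network)
    u <- structure(list(members = u_members,
                        score = table_value(
                          table, bin_index(u_state$d, table$n_bins)),
                        seed = a$seed,
                        trajectory = NULL, density = u_state$d),
                   class = "candidate_complex")
    pick_score <- c(a$score, b$score, u$score)
    # retain the max; ties prefer the union, then the larger set, then the
    # lexicographically smaller member key
    cand3 <- list(a, b, u)
    ord <- order(-pick_score,
                 -c(0, 0, 1),
                 -vapply(cand3, function(cc) length(cc$members), 0L),
                 vapply(cand3, function(cc) cand_key(cc$members), ""))
    winner <- cand3[[ord[1]]]
    candidates <- c(candidates[-best_pair], list(winner))
    keys2 <- vapply(candidates, function(cc) cand_key(cc$members), "")
    candidates <- candidates[!duplicated(keys2)]
  }
  scores <- vapply(candidates, `[[`, 0, "score")
  keys <- vapply(candidates, function(cc) cand_key(cc$members), "")
  candidates[order(-scores, keys, method = "radix")]
}

#' Sweep Qi overlap thresholds and pick the FMMF-optimal one
#'
#' For each threshold, merges the candidates and scores the merged set
#' against the known complexes with the maximal-matching F-score ([fmmf()]);
#' returns the full curve and the argmax (lowest threshold on ties).
#'
#' @param candidates list of `candidate_complex` objects.
#' @param known a [complex_collection] of gold-standard complexes.
#' @param table a [value_table].
#' @param network a [ppi_network].
#' @param thresholds numeric vector of thresholds to test (default 0.2 to
#'   0.9 in steps of 0.025).
#' @param min_size evaluation size floor passed to the node filter.
#' @return object of class `threshold_sweep`: list with `thresholds`,
#'   `fmmf_per_threshold` and `best_threshold`.
#' @export
sweep_thresholds <- function(candidates, known, table, network,
                             thresholds = seq(0.2, 0.9, by = 0.025),
                             min_size = 3) {
  if (length(thresholds) == 0) stop("threshold grid must be nonempty")
  fm <- vapply(thresholds, function(t) {
    merged <- merge_candidates(candidates, t, table, network)
    pred <- lapply(merged, `[[`, "members")
    pred <- filter_to_known_nodes(pred, known, min_size = min_size)
    if (length(pred) == 0) return(0)
    fmmf(pred, known)[["fscore"]]
  }, 0)
  structure(list(thresholds = thresholds, fmmf_per_threshold = fm,
                 best_threshold = thresholds[[which.max(fm)]]),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold_sweep: %d thresholds, best %.3g (FMMF %.4g)\n",
              length(x$thresholds), x$best_threshold,
              max(x$fmmf_per_threshold)))
  invisible(x)
}
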