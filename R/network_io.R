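#' Read a weighted edge list
#'
#' Parses a whitespace- or tab-separated 3-column edge list
#' (`node node weight`). Lines starting with `#` and blank lines are
#' ignored. Duplicate edges keep the maximum weight; self-loops are dropped
#' with a warning.
#'
#' @param path path to the edge-list file.
#' @return a [ppi_network].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop(sprintf("no edges in %s", path))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed network line %d: expected 'node node weight'",
                 idx[which(nf < 3)[1]]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  weight <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(weight) | weight <= 0
  if (any(bad)) {
    stop(sprintf("network line %d: weight must be a positive number",
                 idx[which(bad)[1]]))
  }
  ppi_network(from, to, weight)
}

#' Write a network as a 3-column edge list
#'
#' @param net a [ppi_network].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  ed <- network_edges(net)
  writeLines(sprintf("%s\t%s\t%.17g", ed$from, ed$to, ed$weight), path)
  invisible(path)
}

#' Complex collections
#'
#' An ordered list of named node sets: the gold-standard complexes used for
#' training/evaluation, or a set of predictions. Names default to
#' `Cx1, Cx2, ...` when absent; duplicate members within a complex are
#' collapsed.
#'
#' @param members list of character vectors (one per complex).
#' @param names_ optional character vector of unique complex names.
#' @param scores optional numeric vector of per-complex scores (used for
#'   predicted candidates).
#' @return object of class `complex_collection`: a list with fields
#'   `names`, `members` (list of sorted unique character vectors) and
#'   optionally `scores`.
#' @export
complex_collection <- function(members, names_ = NULL, scores = NULL) {
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  if (any(lengths(members) < 1)) stop("each complex needs >= 1 member")
  if (is.null(names_)) names_ <- paste0("Cx", seq_along(members))
  if (anyDuplicated(names_)) stop("complex names must be unique")
  if (!is.null(scores)) stopifnot(length(scores) == length(members))
  structure(list(names = as.character(names_), members = members,
                 scores = scores),
            class = "complex_collection")
}

#' @export
print.complex_collection <- function(x, ...) {
  sz <- lengths(x$members)
  cat(sprintf("complex_collection: %d complexes\n", length(sz)))
  if (length(sz) > 0) {
    cat(sprintf("  sizes: min %d / median %g / max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' @export
length.complex_collection <- function(x) length(x$members)

#' Read complexes from a one-per-line membership file
#'
#' Each line lists the members of one complex, whitespace/tab separated.
#' Blank lines are skipped with a warning; duplicate members within a line
#' are collapsed. A trailing numeric field is NOT treated specially; use
#' [read_predictions()] for prediction files carrying a score column.
#'
#' @param path path to the complex membership file.
#' @return a [complex_collection].
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop(sprintf("complex file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  blank <- grepl("^\\s*$", lines)
  if (any(blank)) warning(sprintf("skipping %d blank line(s)", sum(blank)))
  lines <- lines[!blank]
  if (length(lines) == 0) stop(sprintf("no complexes in %s", path))
  complex_collection(strsplit(trimws(lines), "[ \t]+"))
}

#' Write complexes (optionally with a score column)
#'
#' One complex per line, members whitespace separated; if the collection
#' carries scores, each line ends with the candidate's value score.
#'
#' @param complexes a [complex_collection].
#' @param path output file path.
#' @export
write_complexes <- function(complexes, path) {
  mem <- vapply(complexes$members, paste, "", collapse = " ")
  if (!is.null(complexes$scores)) {
    writeLines(sprintf("%s %.10g", mem, complexes$scores), path)
  } else {
    writeLines(mem, path)
  }
  invisible(path)
}

#' Read a prediction file written by [write_complexes()] with scores
#'
#' @param path path to a predictions file (members then a final numeric
#'   score column per line).
#' @return a [complex_collection] with `scores` set.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) stop(sprintf("no predictions in %s", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  scores <- vapply(fields, function(f) as.numeric(f[[length(f)]]), 0)
  members <- lapply(fields, function(f) f[-length(f)])
  complex_collection(members, scores = scores)
}

#' Jaccard coefficient between two sets
#' @param a,b character vectors.
#' @export
jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Gold-standard preprocessing
#'
#' Cleans a gold-standard collection against a network the way complex
#' databases (e.g. CORUM-derived sets) are conventionally prepared for
#' supervised complex detection: members absent from the network are removed
#' first; complexes with fewer than `min_size` surviving members or whose
#' surviving members induce a disconnected subgraph are discarded; finally,
#' pairs of complexes whose Jaccard overlap exceeds
#' `jaccard_merge_threshold` are merged (highest-overlap pair first,
#' repeated to a fixed point) so that training rewards, which are defined
#' against one complex at a time, are not contradicted by near-duplicate
#' gold complexes.
#'
#' @param complexes a [complex_collection].
#' @param network a [ppi_network].
#' @param min_size minimum complex size kept (default 3).
#' @param jaccard_merge_threshold merge pairs with Jaccard overlap strictly
#'   above this value (default 0.6).
#' @return a filtered/merged [complex_collection] (possibly empty, with a
#'   warning).
#' @export
preprocess_complexes <- function(complexes, network, min_size = 3,
                                 jaccard_merge_threshold = 0.6) {
  if (length(network_nodes(network)) == 0) stop("network is empty")
  members <- lapply(complexes$members,
                    function(m) intersect(m, network_nodes(network)))
  nm <- complexes$names
  keep <- vapply(members, function(m) {
    length(m) >= min_size && induced_connected(network, m)
  }, logical(1))
  members <- members[keep]
  nm <- nm[keep]
  # iterated pairwise merge: always merge the currently highest-overlap pair
  repeat {
    n <- length(members)
    if (n < 2) break
    best <- c(0L, 0L); best_j <- jaccard_merge_threshold
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        jc <- jaccard(members[[i]], members[[j]])
        if (jc > best_j) {
          best_j <- jc
          best <- c(i, j)
        }
      }
    }
    if (best[1] == 0L) break
    u <- sort(union(members[[best[1]]], members[[best[2]]]))
    merged_name <- paste(nm[best[1]], nm[best[2]], sep = "+")
    members <- c(members[-best], list(u))
    nm <- c(nm[-best], merged_name)
  }
  if (length(members) == 0) {
    warning("no complexes survived preprocessing")
    return(structure(list(names = character(0), members = list(),
                          scores = NULL), class = "complex_collection"))
  }
  complex_collection(members, nm)
}
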