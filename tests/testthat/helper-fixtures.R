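# Shared fixtures and independent brute-force oracles.

# triangle complex embedded in a slightly larger graph
fixture_clique3 <- function() {
  ppi_network(
    from = c("A", "A", "B", "C", "D"),
    to   = c("B", "C", "C", "X", "X"),
    weight = c(1.0, 1.0, 1.0, 0.5, 0.4),
    nodes = "Z")
}

# two disjoint triangles with uniform weights
fixture_two_cliques <- function(w = 0.8) {
  ppi_network(
    from = c("A", "A", "B", "P", "P", "Q"),
    to   = c("B", "C", "C", "Q", "R", "R"),
    weight = rep(w, 6))
}

write_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# all permutations of a vector (tiny n only)
perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

# brute-force maximum-weight bipartite matching over a weight matrix:
# enumerate all injective assignments of the smaller side
brute_matching_weight <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  if (nr > nc) return(brute_matching_weight(t(W)))
  best <- 0
  cols <- utils::combn(nc, nr, simplify = FALSE)
  for (cs in cols) {
    for (p in perms(cs)) {
      best <- max(best, sum(W[cbind(seq_len(nr), p)]))
    }
  }
  best
}

# brute-force per-pair F-similarity (first principles, no package code)
brute_fsim <- function(a, b) {
  ov <- length(intersect(a, b))
  if (ov == 0) return(0)
  p <- ov / length(a); r <- ov / length(b)
  2 / (1 / p + 1 / r)
}

random_member_sets <- function(n, universe, min_size = 2, max_size = 5) {
  lapply(seq_len(n), function(i) {
    sample(universe, sample(min_size:max_size, 1))
  })
}
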