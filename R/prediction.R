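#' Seed edge for prediction
#'
#' For a seed node, the initial subgraph is the edge to its highest-weight
#' neighbor anywhere in the network (ties to the lexicographically smallest
#' identifier). Isolated nodes yield no seed.
#'
#' @param node a node identifier.
#' @param network a [ppi_network].
#' @return character vector `(node, partner)` or `NULL` for isolated nodes.
#' @export
select_prediction_seed_edge <- function(node, network) {
  nb <- network_neighbors(network, node)
  if (length(nb) == 0) return(NULL)
  c(node, names(nb)[which.max(nb)])
}

#' Grow one candidate complex from a seed edge
#'
#' Pure exploitation of the learned value function: at each step every
#' neighbor v of the current subgraph is scored by `V(bin(density(S + v)))`;
#' the best neighbor (lexicographic tie-break) is added when its value is
#' greater than *or equal to* the current subgraph's value
#' `V(bin(density(S)))`, and growth stops when every neighbor would strictly
#' lower the value. The greater-or-equal rule means plateaus keep growing
#' (value-neutral members are accepted); `max_size` caps runaway plateaus
#' such as a constant table.
#'
#' @param seed character vector of length 2, an existing edge.
#' @param table a trained [value_table].
#' @param network a [ppi_network].
#' @param max_size maximum candidate size; `Inf` disables the cap
#'   (default 100).
#' @return object of class `candidate_complex`: list with `members`
#'   (sorted), `score` (table value at the final density bin), `seed`,
#'   `trajectory` (nodes in addition order) and `density`.
#' @export
grow_candidate <- function(seed, table, network, max_size = 100L) {
  stopifnot(length(seed) == 2)
  w <- edge_weight(network, seed[1], seed[2])
  if (w <= 0) stop(sprintf("seed pair %s-%s is not an edge",
                           seed[1], seed[2]))
  members <- sort(seed)
  m <- w
  trajectory <- character(0)
  repeat {
    n <- length(members)
    cur_d <- density_of(n, m)
    cur_val <- table_value(table, bin_index(cur_d, table$n_bins))
    if (n >= max_size) break
    nbs <- subgraph_neighbors(network, members)
    if (length(nbs) == 0) break
    add_w <- vapply(nbs, weight_into, 0, net = network, members = members)
    vals <- vapply(seq_along(nbs), function(i) {
      table_value(table,
                  bin_index(density_of(n + 1L, m + add_w[[i]]),
                            table$n_bins))
    }, 0)
    best <- which.max(vals)  # first max: lexicographically smallest
    if (vals[[best]] < cur_val) break
    trajectory <- c(trajectory, nbs[[best]])
    m <- m + add_w[[best]]
    members <- sort(c(members, nbs[[best]]))
  }
  final_d <- density_of(length(members), m)
  structure(list(members = members,
                 score = table_value(table,
                                     bin_index(final_d, table$n_bins)),
                 seed = seed, trajectory = trajectory, density = final_d),
            class = "candidate_complex")
}

#' @export
print.candidate_complex <- function(x, ...) {
  cat(sprintf("candidate_complex: %d members, score %.4g, seed %s-%s\n",
              length(x$members), x$score, x$seed[1], x$seed[2]))
  invisible(x)
}

#' Grow candidate complexes from every node of the network
#'
#' Every network node contributes one seed edge (its highest-weight
#' incident edge); one candidate is grown per seed. Growth runs are
#' independent, so they are distributed across `workers` processes;
#' partial results are merged and canonically sorted, making the output
#' independent of worker count and scheduling. Candidates with identical
#' member sets are deduplicated (they necessarily carry identical scores).
#'
#' @param network a [ppi_network].
#' @param table a trained [value_table].
#' @param workers number of parallel worker processes (default 1).
#' @param max_size per-candidate size cap, see [grow_candidate()].
#' @return list of [grow_candidate()] results, sorted by score descending
#'   then members lexicographically.
#' @export
predict_all <- function(network, table, workers = 1L, max_size = 100L) {
  nodes <- network_nodes(network)
  grow_one <- function(v) {
    seed <- select_prediction_seed_edge(v, network)
    if (is.null(seed)) return(NULL)
    grow_candidate(seed, table, network, max_size = max_size)
  }
  cands <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(nodes, grow_one, mc.cores = workers)
  } else {
    lapply(nodes, grow_one)
  }
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) return(list())
  key <- vapply(cands, function(cc) paste(cc$members, collapse = "\r"), "")
  cands <- cands[!duplicated(key)]
  key <- key[!duplicated(key)]
  scores <- vapply(cands, `[[`, 0, "score")
  cands[order(-scores, key, method = "radix")]
}

#' Convert candidates to a [complex_collection]
#'
#' @param candidates list of `candidate_complex` objects.
#' @return a [complex_collection] carrying the candidates' value scores.
#' @export
candidates_to_collection <- function(candidates) {
  if (length(candidates) == 0) {
    return(structure(list(names = character(0), members = list(),
                          scores = numeric(0)),
                     class = "complex_collection"))
  }
  complex_collection(lapply(candidates, `[[`, "members"),
                     names_ = paste0("P", seq_along(candidates)),
                     scores = vapply(candidates, `[[`, 0, "score"))
}
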