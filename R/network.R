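#' Weighted undirected protein-interaction networks
#'
#' A `ppi_network` is the environment the learning agent walks on: nodes are
#' proteins, undirected edges carry an interaction-confidence weight expected
#' in (0, 1]. Edges are stored once per unordered pair, self-loops are
#' forbidden, and all weights must be strictly positive. Internally the class
#' keeps a sorted adjacency list so that neighbor enumeration (the inner loop
#' of both training and prediction) is deterministic and O(degree).
#'
#' @param from,to character vectors of endpoint identifiers.
#' @param weight numeric vector of positive edge weights.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers to include.
#' @return An object of class `ppi_network` with components `nodes`
#'   (sorted character vector) and `adj` (named list; `adj[[v]]` is a named
#'   numeric vector of `v`'s neighbors and edge weights, sorted by name).
#' @examples
#' net <- ppi_network(c("A", "B"), c("B", "C"), c(0.8, 0.9))
#' network_neighbors(net, "B")
#' @export
ppi_network <- function(from, to, weight, nodes = character()) {
  stopifnot(length(from) == length(to), length(to) == length(weight))
  from <- as.character(from)
  to <- as.character(to)
  weight <- as.numeric(weight)
  if (anyNA(weight) || any(weight <= 0)) {
    stop("edge weights must be numeric and strictly positive")
  }
  self <- from == to
  if (any(self)) {
    warning(sprintf("dropping %d self-loop(s)", sum(self)))
    nodes <- c(nodes, from[self])  # keep the endpoint as an isolated node
    from <- from[!self]; to <- to[!self]; weight <- weight[!self]
  }
  # canonical unordered pair; duplicates keep the maximum weight
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(weight, key, max)
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    key <- key[keep]
    weight <- as.numeric(w[key])
  }
  all_nodes <- sort(unique(c(a, b, as.character(nodes))))
  adj <- vector("list", length(all_nodes))
  names(adj) <- all_nodes
  for (v in all_nodes) adj[[v]] <- numeric(0)
  for (i in seq_along(a)) {
    adj[[a[i]]][b[i]] <- weight[i]
    adj[[b[i]]][a[i]] <- weight[i]
  }
  adj <- lapply(adj, function(x) {
    if (length(x) == 0) numeric(0) else x[order(names(x))]
  })
  structure(list(nodes = all_nodes, adj = adj), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), network_edge_count(x)))
  invisible(x)
}

#' @rdname ppi_network
#' @param net a `ppi_network`.
#' @export
network_nodes <- function(net) net$nodes

#' @rdname ppi_network
#' @param node a node identifier.
#' @export
network_neighbors <- function(net, node) {
  nb <- net$adj[[node]]
  if (is.null(nb)) stop(sprintf("node '%s' not in network", node))
  nb
}

#' @rdname ppi_network
#' @export
network_edge_count <- function(net) {
  sum(vapply(net$adj, length, integer(1))) %/% 2L
}

#' Edge weight lookup (0 when the pair is not an edge)
#' @inheritParams network_neighbors
#' @param a,b node identifiers.
#' @export
edge_weight <- function(net, a, b) {
  w <- net$adj[[a]][b]
  if (is.null(w) || is.na(w)) 0 else unname(w)
}

#' Edge table of a network
#'
#' @inheritParams network_neighbors
#' @return data.frame with columns `from`, `to`, `weight`; one row per
#'   unordered pair with `from < to`, sorted.
#' @export
network_edges <- function(net) {
  from <- character(0); to <- character(0); weight <- numeric(0)
  for (v in net$nodes) {
    nb <- net$adj[[v]]
    keep <- names(nb) > v
    if (any(keep)) {
      from <- c(from, rep(v, sum(keep)))
      to <- c(to, names(nb)[keep])
      weight <- c(weight, unname(nb[keep]))
    }
  }
  data.frame(from = from, to = to, weight = weight,
             stringsAsFactors = FALSE)
}

# Sum of weights from node v into the member set (incremental density step).
weight_into <- function(net, v, members) {
  nb <- net$adj[[v]]
  if (length(nb) == 0) return(0)
  sum(nb[names(nb) %in% members])
}

# All neighbors of a member set (excluding members), sorted.
subgraph_neighbors <- function(net, members) {
  nb <- unique(unlist(lapply(unname(members), function(v) names(net$adj[[v]])),
                      use.names = FALSE))
  sort(setdiff(nb, members))
}

# Is the subgraph induced by `members` connected? (BFS over induced edges)
induced_connected <- function(net, members) {
  members <- unique(members)
  if (length(members) <= 1) return(TRUE)
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(v) {
      intersect(names(net$adj[[v]]), members)
    }), use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(members)
}
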