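#' Configuration for planted-complex network simulation
#'
#' Describes a synthetic weighted network built from planted complexes of
#' varied topology, the substrate used to exercise and test every pipeline
#' stage without external data. Topologies: `clique` (every pair
#' connected), `chain` (path), `star` (hub and leaves), `ring` (cycle) and
#' `dense` (random spanning tree plus ~half of the remaining pairs — a
#' mixed-density community). Intra-complex edge weights emulate
#' high-confidence interactions; optional weak inter-complex edges emulate
#' background noise.
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer (min, max) complex sizes, both >= 3.
#' @param topology_mix named numeric proportions over
#'   `c(clique, chain, star, ring, dense)`.
#' @param intra_weight_range weight range for intra-complex edges,
#'   within (0, 1].
#' @param inter_edge_prob probability of a weak edge between any
#'   cross-complex node pair (forced to 0 when `disconnected`).
#' @param inter_weight_range weight range for inter-complex edges.
#' @param disconnected when `TRUE` (default) the network is a disjoint
#'   union of the planted complexes.
#' @param train_fraction fraction of complexes assigned to the training
#'   split.
#' @param rng_seed integer seed; the whole construction is deterministic
#'   given the config.
#' @return list of class `planted_config`.
#' @export
planted_config <- function(n_complexes = 14L,
                           size_range = c(3L, 6L),
                           topology_mix = c(clique = 0.4, chain = 0.15,
                                            star = 0.15, ring = 0.15,
                                            dense = 0.15),
                           intra_weight_range = c(0.6, 1.0),
                           inter_edge_prob = 0,
                           inter_weight_range = c(0.05, 0.3),
                           disconnected = TRUE,
                           train_fraction = 0.5,
                           rng_seed = 1L) {
  stopifnot(n_complexes >= 1, length(size_range) == 2,
            size_range[1] >= 3, size_range[1] <= size_range[2],
            all(intra_weight_range > 0), all(intra_weight_range <= 1),
            intra_weight_range[1] <= intra_weight_range[2],
            inter_edge_prob >= 0, inter_edge_prob < 1,
            train_fraction > 0, train_fraction < 1)
  topo <- c("clique", "chain", "star", "ring", "dense")
  if (!all(names(topology_mix) %in% topo)) {
    stop("topology_mix names must be among clique/chain/star/ring/dense")
  }
  if (disconnected) inter_edge_prob <- 0
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 topology_mix = topology_mix / sum(topology_mix),
                 intra_weight_range = intra_weight_range,
                 inter_edge_prob = inter_edge_prob,
                 inter_weight_range = inter_weight_range,
                 disconnected = disconnected,
                 train_fraction = train_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "planted_config")
}

# edge skeleton (pairs of 1-based local indices) for one topology
topology_edges <- function(topology, size, order) {
  v <- order  # a permutation of 1:size, randomizing which node plays which
  pairs <- switch(
    topology,
    clique = t(utils::combn(seq_len(size), 2)),
    chain = cbind(v[-size], v[-1]),
    star = cbind(rep(v[1], size - 1), v[-1]),
    ring = rbind(cbind(v[-size], v[-1]), c(v[size], v[1])),
    dense = {
      tree <- cbind(v[-1], vapply(2:size, function(i) {
        v[sample.int(i - 1, 1)]
      }, 0L))
      rest <- t(utils::combn(seq_len(size), 2))
      key_tree <- paste(pmin(tree[, 1], tree[, 2]),
                        pmax(tree[, 1], tree[, 2]))
      key_rest <- paste(rest[, 1], rest[, 2])
      extra <- rest[!(key_rest %in% key_tree) &
                      stats::runif(nrow(rest)) < 0.5, , drop = FALSE]
      rbind(tree, extra)
    },
    stop(sprintf("unknown topology '%s'", topology)))
  pairs
}

#' Generate a planted-complex weighted network
#'
#' Builds the network, the ground-truth complex collection and a seeded
#' disjoint train/test split. Every planted complex is internally connected
#' with at least 3 nodes, so with `disconnected = TRUE` the collection
#' passes [preprocess_complexes()] unchanged.
#'
#' @param config a [planted_config].
#' @return list with `network` (a [ppi_network]), `complexes` (all planted
#'   complexes, a [complex_collection]), `train` and `test`
#'   ([complex_collection]s), `topologies` (character vector per complex).
#' @export
generate_planted <- function(config = planted_config()) {
  topo_names <- names(config$topology_mix)
  with_private_seed(config$rng_seed, {
    size_values <- seq(config$size_range[1], config$size_range[2])
    sizes <- size_values[sample.int(length(size_values),
                                    config$n_complexes, replace = TRUE)]
    topologies <- sample(topo_names, config$n_complexes, replace = TRUE,
                         prob = config$topology_mix)
    members <- vector("list", config$n_complexes)
    from <- character(0); to <- character(0); weight <- numeric(0)
    for (i in seq_len(config$n_complexes)) {
      size <- sizes[[i]]
      ids <- sprintf("c%02d_%02d", i, seq_len(size))
      members[[i]] <- ids
      ord <- sample.int(size)
      pairs <- topology_edges(topologies[[i]], size, ord)
      w <- stats::runif(nrow(pairs), config$intra_weight_range[1],
                        config$intra_weight_range[2])
      from <- c(from, ids[pairs[, 1]])
      to <- c(to, ids[pairs[, 2]])
      weight <- c(weight, w)
    }
    if (config$inter_edge_prob > 0) {
      all_ids <- unlist(members, use.names = FALSE)
      owner <- rep(seq_along(members), lengths(members))
      cross <- utils::combn(seq_along(all_ids), 2)
      cross <- cross[, owner[cross[1, ]] != owner[cross[2, ]], drop = FALSE]
      pick <- stats::runif(ncol(cross)) < config$inter_edge_prob
      if (any(pick)) {
        cross <- cross[, pick, drop = FALSE]
        from <- c(from, all_ids[cross[1, ]])
        to <- c(to, all_ids[cross[2, ]])
        weight <- c(weight, stats::runif(ncol(cross),
                                         config$inter_weight_range[1],
                                         config$inter_weight_range[2]))
      }
    }
    n_train <- max(1L, floor(config$train_fraction * config$n_complexes))
    train_idx <- sort(sample.int(config$n_complexes, n_train))
  })
  network <- ppi_network(from, to, weight)
  complexes <- complex_collection(members)
  test_idx <- setdiff(seq_len(config$n_complexes), train_idx)
  list(network = network,
       complexes = complexes,
       train = complex_collection(members[train_idx],
                                  complexes$names[train_idx]),
       test = complex_collection(members[test_idx],
                                 complexes$names[test_idx]),
       topologies = topologies)
}

#' Toy-network preset: 14 disconnected complexes, 62 nodes, 78 edges
#'
#' A fixed mixed-topology layout at the scale of the small disconnected
#' benchmark network used to validate the method end to end: 14 planted
#' complexes (five 4- or 5-cliques, two triangles, three rings, a star, a
#' chain and two mixed-density communities) totalling exactly 62 nodes and
#' 78 edges, split 7 training / 7 testing with every topology represented
#' on both sides. Edge weights are drawn uniformly from
#' `intra_weight_range` under `rng_seed`; the layout itself is fixed.
#'
#' @param rng_seed integer seed for the edge weights.
#' @param intra_weight_range weight range for the (all intra-complex)
#'   edges.
#' @return same structure as [generate_planted()].
#' @export
toy_network_preset <- function(rng_seed = 1L,
                               intra_weight_range = c(0.6, 1.0)) {
  layout <- list(
    list(topology = "clique", size = 4L),
    list(topology = "clique", size = 4L),
    list(topology = "clique", size = 4L),
    list(topology = "clique", size = 4L),
    list(topology = "clique", size = 5L),
    list(topology = "dense5", size = 5L),
    list(topology = "clique", size = 3L),
    list(topology = "clique", size = 3L),
    list(topology = "ring", size = 4L),
    list(topology = "ring", size = 5L),
    list(topology = "ring", size = 6L),
    list(topology = "star", size = 5L),
    list(topology = "chain", size = 4L),
    list(topology = "dense6", size = 6L))
  # fixed edge skeletons for the two mixed-density communities
  fixed_pairs <- function(topology, size) {
    switch(topology,
           dense5 = rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 4),
                          c(4, 5), c(1, 4), c(3, 5)),
           dense6 = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                          c(1, 3), c(2, 5), c(3, 6)),
           topology_edges(topology, size, seq_len(size)))
  }
  from <- character(0); to <- character(0); nedges <- integer(0)
  members <- vector("list", length(layout))
  for (i in seq_along(layout)) {
    size <- layout[[i]]$size
    ids <- sprintf("c%02d_%02d", i, seq_len(size))
    members[[i]] <- ids
    pairs <- fixed_pairs(layout[[i]]$topology, size)
    from <- c(from, ids[pairs[, 1]])
    to <- c(to, ids[pairs[, 2]])
    nedges <- c(nedges, nrow(pairs))
  }
  weight <- with_private_seed(rng_seed, {
    stats::runif(length(from), intra_weight_range[1],
                 intra_weight_range[2])
  })
  network <- ppi_network(from, to, weight)
  complexes <- complex_collection(members)
  train_idx <- c(1L, 5L, 6L, 8L, 10L, 12L, 13L)
  test_idx <- setdiff(seq_along(layout), train_idx)
  list(network = network,
       complexes = complexes,
       train = complex_collection(members[train_idx],
                                  complexes$names[train_idx]),
       test = complex_collection(members[test_idx],
                                 complexes$names[test_idx]),
       topologies = vapply(layout, `[[`, "", "topology"))
}

#' Seven-node demonstration network
#'
#' A tiny hand-built fixture for walking the training and prediction
#' arithmetic by hand: 7 nodes, 11 weighted edges, one known complex
#' {A, B, C, E}. The seed edge A-B has weight 0.8, so the two-node state
#' has density 0.8; the densities along the canonical growth trajectory
#' are 0.8 ({A,B}), 0.57 ({A,B,C}) and 0.38 ({A,B,C,E}). Weights not
#' pinned down by those densities are fixture choices.
#'
#' @return list with `network` (a [ppi_network]) and `complexes` (a
#'   [complex_collection] holding the single known complex).
#' @export
demo_network <- function() {
  edges <- data.frame(
    from = c("A", "A", "B", "B", "C", "C", "E", "D", "D", "D", "F"),
    to   = c("B", "C", "C", "D", "E", "G", "F", "E", "F", "G", "G"),
    weight = c(0.80, 0.50, 0.41, 0.30, 0.57, 0.30, 0.30, 0.35, 0.45,
               0.40, 0.50),
    stringsAsFactors = FALSE)
  list(network = ppi_network(edges$from, edges$to, edges$weight),
       complexes = complex_collection(list(c("A", "B", "C", "E")),
                                      names_ = "demo"))
}
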