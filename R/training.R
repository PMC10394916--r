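#' Training configuration
#'
#' Bundles the value-iteration hyperparameters. Defaults are the method's
#' stated operating point: discount 0.5, rewards +0.2 (correct neighbor),
#' -0.2 (wrong neighbor), 0 (terminate), 20 density bins. Training repeats
#' full passes ("epochs") over the complex set until the largest absolute
#' value change in an epoch drops below `tolerance` or `max_epochs` is
#' reached.
#'
#' @param gamma discount factor (default 0.5).
#' @param reward_correct,reward_wrong,reward_terminal reward scheme
#'   (defaults +0.2 / -0.2 / 0).
#' @param n_bins number of density bins (default 20).
#' @param tolerance epoch-level convergence tolerance on the max absolute
#'   value change (default 1e-3).
#' @param max_epochs maximum number of passes over the complex set
#'   (default 50).
#' @param rng_seed integer seed controlling the shuffling of start nodes.
#' @return list of class `training_config`.
#' @export
training_config <- function(gamma = 0.5, reward_correct = 0.2,
                            reward_wrong = -0.2, reward_terminal = 0,
                            n_bins = 20L, tolerance = 1e-3,
                            max_epochs = 50L, rng_seed = 1L) {
  stopifnot(gamma >= 0, gamma < 1, tolerance > 0, max_epochs >= 1)
  structure(list(gamma = gamma, reward_correct = reward_correct,
                 reward_wrong = reward_wrong,
                 reward_terminal = reward_terminal,
                 n_bins = as.integer(n_bins), tolerance = tolerance,
                 max_epochs = as.integer(max_epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Seed edge for a training episode
#'
#' The initial subgraph of an episode is an edge between the episode's start
#' node and the start node's highest-edge-weight neighbor *within the
#' training complex* (an out-of-complex partner would poison the target
#' subgraph from step zero). Weight ties break to the lexicographically
#' smallest neighbor identifier.
#'
#' @param complex_members character vector, the training complex.
#' @param start_node a member of `complex_members`.
#' @param network a [ppi_network].
#' @return character vector of length 2 `(start_node, partner)`, or `NULL`
#'   (with a warning) when the start node has no in-complex neighbor.
#' @export
select_training_seed_edge <- function(complex_members, start_node, network) {
  if (!start_node %in% complex_members) {
    stop(sprintf("start node '%s' is not in the complex", start_node))
  }
  nb <- network_neighbors(network, start_node)
  nb <- nb[names(nb) %in% setdiff(complex_members, start_node)]
  if (length(nb) == 0) {
    warning(sprintf("start node '%s' is isolated within its complex; %s",
                    start_node, "episode skipped"))
    return(NULL)
  }
  # adjacency is name-sorted, so which.max already breaks ties
  # lexicographically
  c(start_node, names(nb)[which.max(nb)])
}

#' One training episode over a single complex
#'
#' Grows a subgraph from the seed edge. At every step all network neighbors
#' of the current subgraph are evaluated: each neighbor is temporarily
#' added, the tentative next density computed, and the action value
#' `reward + gamma * V(next bin)` formed, where the reward is
#' `reward_correct` if the neighbor belongs to the training complex and
#' `reward_wrong` otherwise. The terminal "imaginary node" action
#' (`reward_terminal`, next state = current state) is appended last. The
#' current density bin is overwritten with the max action value; if the
#' argmax is the terminal action the episode ends, otherwise the argmax
#' neighbor is permanently added (even when it is a wrong node) and the
#' loop repeats.
#'
#' @inheritParams select_training_seed_edge
#' @param table a [value_table] (updated values are carried in the return).
#' @return list with `table` (updated) and `trace`, a data.frame with one
#'   row per step: `n`, `density`, `bin`, `chosen` (added node or
#'   `"<terminal>"`), `reward`, `updated_value`.
#' @export
run_training_episode <- function(complex_members, start_node, table,
                                 network) {
  seed <- select_training_seed_edge(complex_members, start_node, network)
  if (is.null(seed)) {
    return(list(table = table, trace = NULL))
  }
  members <- sort(seed)
  m <- edge_weight(network, seed[1], seed[2])
  steps <- list()
  repeat {
    n <- length(members)
    d <- density_of(n, m)
    cur_bin <- bin_index(d, table$n_bins)
    nbs <- subgraph_neighbors(network, members)
    add_w <- vapply(nbs, weight_into, 0, net = network, members = members)
    rewards <- ifelse(nbs %in% complex_members,
                      table$reward_correct, table$reward_wrong)
    next_d <- vapply(seq_along(nbs), function(i) {
      density_of(n + 1L, m + add_w[[i]])
    }, 0)
    next_bins <- if (length(nbs) > 0) bin_index(next_d, table$n_bins)
                 else integer(0)
    # terminal action last: reward_terminal, next state = current state
    up <- bellman_update(table, cur_bin,
                         c(rewards, table$reward_terminal),
                         c(next_bins, cur_bin))
    table <- up$table
    terminal <- up$best_action > length(nbs)
    steps[[length(steps) + 1L]] <- data.frame(
      n = n, density = d, bin = cur_bin,
      chosen = if (terminal) "<terminal>" else nbs[[up$best_action]],
      reward = if (terminal) table$reward_terminal else
        rewards[[up$best_action]],
      updated_value = up$updated_value,
      stringsAsFactors = FALSE)
    if (terminal) break
    v <- nbs[[up$best_action]]
    m <- m + add_w[[up$best_action]]
    members <- sort(c(members, v))
  }
  list(table = table, trace = do.call(rbind, steps))
}

#' Train the value table over a complex collection
#'
#' Runs value-iteration training: each epoch replays one episode per (node
#' of each complex), with the start-node order within each complex shuffled
#' deterministically from `rng_seed` (the first node of the first pass is
#' the "initial random node"; the order is drawn once and replayed
#' identically every epoch, making each epoch the same deterministic update
#' map). Training stops when an epoch's maximum absolute value change —
#' measured between the value-table snapshots at the start and end of the
#' epoch — falls below `tolerance`, or after `max_epochs` epochs.
#' Within-epoch updates legitimately keep fluctuating at a fixed point
#' (the terminal action geometrically decays final-state bins, which
#' mid-trajectory visits restore), which is why convergence is assessed on
#' the epoch map, not on single updates.
#'
#' @param complexes a preprocessed, nonempty [complex_collection].
#' @param network a [ppi_network].
#' @param config a [training_config].
#' @return list of class `training_result` with `table` (the trained
#'   [value_table]), `history` (data.frame of every update event: `epoch`,
#'   `update`, `bin`, `density`, `value`), `epoch_max_change` (numeric per
#'   epoch), `converged` (logical) and `epochs_run`.
#' @export
train <- function(complexes, network, config = training_config()) {
  if (length(complexes$members) == 0) stop("complex collection is empty")
  table <- value_table(n_bins = config$n_bins, gamma = config$gamma,
                       reward_correct = config$reward_correct,
                       reward_wrong = config$reward_wrong,
                       reward_terminal = config$reward_terminal,
                       trained_on = sprintf("%d complexes / %d nodes",
                                            length(complexes$members),
                                            length(network_nodes(network))))
  hist_rows <- list()
  epoch_max_change <- numeric(0)
  update_count <- 0L
  converged <- FALSE
  start_orders <- with_private_seed(config$rng_seed, {
    lapply(complexes$members, sample)
  })
  for (epoch in seq_len(config$max_epochs)) {
    snapshot <- table$values
    for (ci in seq_along(complexes$members)) {
      cx <- complexes$members[[ci]]
      for (start_node in start_orders[[ci]]) {
        ep <- suppressWarnings(
          run_training_episode(cx, start_node, table, network))
        table <- ep$table
        if (is.null(ep$trace)) next
        update_count <- update_count + nrow(ep$trace)
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          epoch = epoch,
          bin = ep$trace$bin,
          density = ep$trace$density,
          value = ep$trace$updated_value)
      }
    }
    max_change <- max(abs(table$values - snapshot))
    epoch_max_change <- c(epoch_max_change, max_change)
    if (max_change < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  history <- do.call(rbind, hist_rows)
  if (!is.null(history)) history$update <- seq_len(nrow(history))
  structure(list(table = table, history = history,
                 epoch_max_change = epoch_max_change,
                 converged = converged,
                 epochs_run = length(epoch_max_change)),
            class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf("training_result: %d epoch(s), %s (last max change %.2g)\n",
              x$epochs_run,
              if (x$converged) "converged" else "not converged",
              if (length(x$epoch_max_change)) utils::tail(
                x$epoch_max_change, 1) else NA_real_))
  invisible(x)
}
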