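#' Subgraph density state
#'
#' The agent observes a single topological feature of its current subgraph:
#' the weighted density d = 2m / (n (n - 1)), where n is the number of nodes
#' and m the sum of induced edge weights. With all weights <= 1 the density
#' lies in [0, 1]. For n < 2 the density is defined as 0 (growth always
#' starts from a seed edge, so such states do not arise in practice).
#'
#' @param members character vector of node identifiers (a subset of the
#'   network's nodes).
#' @param network a [ppi_network].
#' @return object of class `subgraph_state`: list with `members` (sorted),
#'   `n`, `m` (summed induced edge weight) and `d` (density).
#' @examples
#' net <- ppi_network(c("A"), c("B"), 0.8)
#' density_state(c("A", "B"), net)$d  # 0.8
#' @export
density_state <- function(members, network) {
  members <- sort(unique(as.character(members)))
  missing <- setdiff(members, network_nodes(network))
  if (length(missing) > 0) {
    stop(sprintf("member(s) not in network: %s",
                 paste(missing, collapse = ", ")))
  }
  n <- length(members)
  m <- 0
  if (n >= 2) {
    for (v in members) {
      nb <- network$adj[[v]]
      m <- m + sum(nb[names(nb) %in% members])
    }
    m <- m / 2
  }
  d <- if (n < 2) 0 else 2 * m / (n * (n - 1))
  structure(list(members = members, n = n, m = m, d = d),
            class = "subgraph_state")
}

# internal fast path: density from precomputed (n, m)
density_of <- function(n, m) if (n < 2) 0 else 2 * m / (n * (n - 1))

#' Discretize a density into a value-table bin
#'
#' Bin `b` (0-based) covers the half-open interval `[b/n_bins, (b+1)/n_bins)`
#' with the top bin closed at 1, so every density in [0, 1] maps to exactly
#' one of the `n_bins` bins. Densities above 1 (possible only if edge
#' weights exceed 1) clamp to the top bin with a warning.
#'
#' @param d density, >= 0.
#' @param n_bins number of bins (default 20).
#' @return 0-based bin index in `0:(n_bins - 1)`.
#' @export
bin_index <- function(d, n_bins = 20L) {
  if (any(d < 0)) stop("density must be non-negative")
  if (any(d > 1)) {
    warning("density > 1 clamped to top bin")
    d <- pmin(d, 1)
  }
  pmin(as.integer(floor(d * n_bins)), n_bins - 1L)
}

#' Tabular value function over density bins
#'
#' The learned policy's backbone: a map from discretized subgraph density to
#' the expected discounted return of being at that density on the way to a
#' true complex. All values start at 0. With the default reward scheme
#' (+0.2 correct / -0.2 wrong / 0 terminal) and discount gamma = 0.5 every
#' stored value is bounded by `reward_correct / (1 - gamma) = 0.4` in
#' absolute value (geometric-series bound).
#'
#' @param n_bins number of density bins (default 20).
#' @param gamma discount factor in [0, 1) (default 0.5).
#' @param reward_correct reward for adding a neighbor belonging to the
#'   training complex (default +0.2).
#' @param reward_wrong reward for adding a neighbor outside the training
#'   complex (default -0.2).
#' @param reward_terminal reward for the terminal "imaginary node" action
#'   (default 0).
#' @param trained_on free-text provenance label stored with the table.
#' @return object of class `value_table` with fields `n_bins`, `values`
#'   (numeric vector of length `n_bins`, 0-based bins), `gamma`,
#'   `reward_correct`, `reward_wrong`, `reward_terminal`, `trained_on`.
#' @export
value_table <- function(n_bins = 20L, gamma = 0.5, reward_correct = 0.2,
                        reward_wrong = -0.2, reward_terminal = 0,
                        trained_on = "") {
  stopifnot(n_bins >= 1, gamma >= 0, gamma < 1)
  structure(list(n_bins = as.integer(n_bins),
                 values = numeric(n_bins),
                 gamma = gamma,
                 reward_correct = reward_correct,
                 reward_wrong = reward_wrong,
                 reward_terminal = reward_terminal,
                 trained_on = trained_on),
            class = "value_table")
}

#' @export
print.value_table <- function(x, ...) {
  cat(sprintf(paste0("value_table: %d bins, gamma=%g, ",
                     "rewards %+g/%+g/%g, %d bin(s) visited\n"),
              x$n_bins, x$gamma, x$reward_correct, x$reward_wrong,
              x$reward_terminal, sum(x$values != 0)))
  invisible(x)
}

#' Look up the value of a density bin
#' @param table a [value_table].
#' @param bin 0-based bin index.
#' @export
table_value <- function(table, bin) {
  table$values[[bin + 1L]]
}

#' Synchronous Bellman update at one state
#'
#' Applies the deterministic value-iteration update
#' `V(s) <- max_a (R(a) + gamma * V(s'))` at the current state's bin. Each
#' action is a pair (reward, next-state bin); next-state values are read
#' from the table *before* the update (synchronous within one step). The
#' stored value at the current bin is overwritten with the maximum action
#' value. Ties go to the lowest action index.
#'
#' @param table a [value_table].
#' @param current_bin 0-based bin of the current state.
#' @param rewards numeric vector of per-action rewards.
#' @param next_bins integer vector of per-action next-state bins (0-based),
#'   parallel to `rewards`.
#' @return list with `table` (updated), `updated_value` (the new value at
#'   `current_bin`), `best_action` (1-based argmax index, lowest on ties)
#'   and `action_values`.
#' @export
bellman_update <- function(table, current_bin, rewards, next_bins) {
  if (length(rewards) == 0) stop("action list must be nonempty")
  stopifnot(length(rewards) == length(next_bins))
  av <- rewards + table$gamma * table$values[next_bins + 1L]
  best <- which.max(av)  # which.max takes the first maximum: lowest index
  table$values[[current_bin + 1L]] <- av[[best]]
  list(table = table, updated_value = av[[best]], best_action = best,
       action_values = av)
}

#' Save / load a value table (JSON)
#'
#' Persistence enables transfer learning: a table trained on one network can
#' seed prediction on another. The JSON round-trip preserves bin edges,
#' values, gamma and the reward scheme exactly.
#'
#' @param table a [value_table].
#' @param path file path for the JSON table.
#' @export
save_value_table <- function(table, path) {
  obj <- list(format = "rlcomplex-value-table",
              version = 1L,
              n_bins = table$n_bins,
              bin_edges = seq(0, 1, length.out = table$n_bins + 1L),
              values = table$values,
              gamma = table$gamma,
              rewards = list(correct = table$reward_correct,
                             wrong = table$reward_wrong,
                             terminal = table$reward_terminal),
              trained_on = table$trained_on)
  # I(17) significant digits: lossless round-trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_value_table
#' @param n_bins if not `NULL`, require the loaded table to have exactly
#'   this many bins.
#' @export
load_value_table <- function(path, n_bins = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "rlcomplex-value-table") {
    stop(sprintf("%s is not a value-table file", path))
  }
  req <- c("n_bins", "values", "gamma", "rewards")
  miss <- setdiff(req, names(obj))
  if (length(miss) > 0) {
    stop(sprintf("value-table file missing field(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (length(obj$values) != obj$n_bins) {
    stop(sprintf("value-table file has %d values for %d bins",
                 length(obj$values), obj$n_bins))
  }
  if (!is.null(n_bins) && obj$n_bins != n_bins) {
    stop(sprintf("expected %d bins, file has %d", n_bins, obj$n_bins))
  }
  tab <- value_table(n_bins = obj$n_bins, gamma = obj$gamma,
                     reward_correct = obj$rewards[["correct"]],
                     reward_wrong = obj$rewards[["wrong"]],
                     reward_terminal = obj$rewards[["terminal"]],
                     trained_on = if (is.null(obj$trained_on)) "" else
                       obj$trained_on)
  tab$values <- as.numeric(obj$values)
  tab
}
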