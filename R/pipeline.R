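#' Pipeline configuration
#'
#' Collects all inputs and options of a full run:
#' train -> predict -> merge/sweep -> evaluate. Either `network` /
#' `complexes` objects or file paths may be supplied. When `value_table`
#' (an object or a saved JSON path) is given, training is skipped and the
#' supplied table drives prediction — the transfer-learning mode.
#'
#' @param network a [ppi_network] or path to an edge-list file.
#' @param complexes a [complex_collection] or path to a membership file
#'   (the gold standard; preprocessed and used for training and sweeping).
#' @param out_dir output directory (created if absent).
#' @param value_table optional pre-trained [value_table] or path to one.
#' @param training a [training_config].
#' @param workers prediction worker processes.
#' @param max_size prediction size cap.
#' @param sweep_grid Qi thresholds tested; when of length 1, the sweep is
#'   skipped and the single threshold used directly.
#' @param eval_complexes optional [complex_collection] (or path) evaluated
#'   against instead of the training gold standard (e.g. a held-out test
#'   split or the full known set).
#' @param min_size evaluation/preprocessing size floor.
#' @param qi_tau Qi et al. F-score match threshold.
#' @param preprocess whether to run [preprocess_complexes()] on the gold
#'   standard (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(network, complexes, out_dir,
                            value_table = NULL,
                            training = training_config(),
                            workers = 1L, max_size = 100L,
                            sweep_grid = seq(0.2, 0.9, by = 0.025),
                            eval_complexes = NULL,
                            min_size = 3, qi_tau = 0.25,
                            preprocess = TRUE) {
  structure(list(network = network, complexes = complexes,
                 out_dir = out_dir, value_table = value_table,
                 training = training, workers = as.integer(workers),
                 max_size = max_size, sweep_grid = sweep_grid,
                 eval_complexes = eval_complexes, min_size = min_size,
                 qi_tau = qi_tau, preprocess = preprocess),
            class = "pipeline_config")
}

resolve_network <- function(x) {
  if (inherits(x, "ppi_network")) x else read_network(x)
}
resolve_complexes <- function(x) {
  if (inherits(x, "complex_collection")) x else read_complexes(x)
}

#' Run the full detection pipeline
#'
#' Executes every stage and writes all artifacts into `out_dir`:
#' `value_table.json`, `history.tsv` (per-update value series),
#' `convergence.tsv` (epoch max changes), `density_value.tsv`
#' (bin-density/value diagnostic pairs with their rank correlation in
#' `diagnostics.json`), `predictions_raw.txt`, `sweep.tsv`,
#' `predictions.txt` (merged, at the best threshold), `evaluation.tsv` and
#' a `manifest.json` recording parameters and seeds for exact re-runs.
#'
#' @param config a [pipeline_config].
#' @return (invisibly) a list with the in-memory results: `table`,
#'   `training` (NULL in transfer mode), `candidates`, `merged`, `sweep`,
#'   `report`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  net <- resolve_network(config$network)
  gold_raw <- resolve_complexes(config$complexes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  gold <- if (config$preprocess) {
    preprocess_complexes(gold_raw, net, min_size = config$min_size)
  } else gold_raw
  if (length(gold$members) == 0) {
    stop("stage preprocess: no gold-standard complexes survived")
  }

  transfer <- !is.null(config$value_table)
  tr <- NULL
  if (transfer) {
    tab <- if (inherits(config$value_table, "value_table")) {
      config$value_table
    } else {
      load_value_table(config$value_table)
    }
  } else {
    tr <- tryCatch(train(gold, net, config$training),
                   error = function(e) {
                     stop(sprintf("stage train: %s", conditionMessage(e)))
                   })
    tab <- tr$table
    if (!is.null(tr$history)) {
      utils::write.table(tr$history, out("history.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      data.frame(epoch = seq_along(tr$epoch_max_change),
                 max_change = tr$epoch_max_change),
      out("convergence.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  save_value_table(tab, out("value_table.json"))

  diag <- report_diagnostics(tr, tab)
  utils::write.table(diag$density_value, out("density_value.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rank_correlation = diag$rank_correlation,
                            converged = if (is.null(tr)) NA else
                              tr$converged),
                       out("diagnostics.json"), auto_unbox = TRUE,
                       digits = NA)

  cands <- tryCatch(
    predict_all(net, tab, workers = config$workers,
                max_size = config$max_size),
    error = function(e) {
      stop(sprintf("stage predict: %s", conditionMessage(e)))
    })
  write_complexes(candidates_to_collection(cands),
                  out("predictions_raw.txt"))

  if (length(config$sweep_grid) > 1) {
    sweep <- sweep_thresholds(cands, gold, tab, net,
                              thresholds = config$sweep_grid,
                              min_size = config$min_size)
    utils::write.table(
      data.frame(threshold = sweep$thresholds,
                 fmmf = sweep$fmmf_per_threshold),
      out("sweep.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    best_t <- sweep$best_threshold
  } else {
    sweep <- NULL
    best_t <- config$sweep_grid
  }
  merged <- merge_candidates(cands, best_t, tab, net)
  write_complexes(candidates_to_collection(merged), out("predictions.txt"))

  eval_gold <- if (is.null(config$eval_complexes)) gold else
    resolve_complexes(config$eval_complexes)
  report <- evaluate_all(lapply(merged, `[[`, "members"), eval_gold,
                         min_size = config$min_size,
                         qi_tau = config$qi_tau)
  utils::write.table(report, out("evaluation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    transfer_mode = transfer,
    training = unclass(config$training),
    workers = config$workers,
    max_size = config$max_size,
    sweep_grid = config$sweep_grid,
    best_threshold = best_t,
    min_size = config$min_size,
    qi_tau = config$qi_tau,
    n_gold = length(gold$members),
    n_candidates = length(cands),
    n_merged = length(merged))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(table = tab, training = tr, candidates = cands,
                 merged = merged, sweep = sweep, report = report,
                 best_threshold = best_t, out_dir = config$out_dir))
}

#' Training diagnostics
#'
#' Summarizes what the agent learned: the per-bin value series and epoch
#' max-change series from training (when available), and the
#' (bin density, value) pairs of the visited bins together with their
#' Spearman rank correlation — on complex-rich substrates higher densities
#' should carry higher values.
#'
#' @param training_result a `training_result` from [train()], or `NULL`
#'   (transfer mode: only table-level diagnostics are produced).
#' @param table the trained [value_table]; defaults to the one inside
#'   `training_result`.
#' @return list with `density_value` (data.frame: `bin`, `density`
#'   (bin midpoint), `value`, visited bins only), `rank_correlation`
#'   (Spearman, `NA` when fewer than 3 bins were visited),
#'   `epoch_max_change`, and `history`.
#' @export
report_diagnostics <- function(training_result,
                               table = training_result$table) {
  visited <- which(table$values != 0) - 1L
  if (!is.null(training_result) && !is.null(training_result$history)) {
    visited <- sort(unique(c(visited, training_result$history$bin)))
  }
  mid <- (visited + 0.5) / table$n_bins
  dv <- data.frame(bin = visited, density = mid,
                   value = table$values[visited + 1L])
  rc <- if (nrow(dv) >= 3) {
    suppressWarnings(stats::cor(dv$density, dv$value,
                                method = "spearman"))
  } else NA_real_
  list(density_value = dv, rank_correlation = rc,
       epoch_max_change = if (is.null(training_result)) numeric(0) else
         training_result$epoch_max_change,
       history = if (is.null(training_result)) NULL else
         training_result$history)
}
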