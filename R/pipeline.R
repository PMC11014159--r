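#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end pipeline — load (or generate)
#' embeddings, collapse segments, build the k-NN graph, train, evaluate —
#' with recorded defaults. The effective configuration is echoed into
#' every artifact the pipeline writes, so each report is reproducible
#' from its own metadata.
#'
#' @param table_path Path to an embedding-table CSV/TSV (`NULL` when a
#'   table object is passed to [run_pipeline()] directly).
#' @param mode `"auto"` (cv when the table has folds, holdout otherwise),
#'   `"cv"` or `"holdout"`.
#' @param arch,k,n_hidden,heads,dropout Model and graph hyperparameters.
#' @param metric,symmetrized Graph construction options.
#' @param lr,weight_decay,epochs,seed Training options.
#' @param out_dir Output directory for artifacts (`NULL`: no files).
#' @return A `run_config` list.
#' @export
run_config <- function(table_path = NULL, mode = c("auto", "cv", "holdout"),
                       arch = "gcn", k = 6L, n_hidden = 32L, heads = 10L,
                       dropout = 0.5, metric = "euclidean",
                       symmetrized = TRUE, lr = 0.001, weight_decay = 5e-4,
                       epochs = 300L, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  arch <- match.arg(tolower(arch), c("gcn", "sage", "gat"))
  metric <- match.arg(metric, c("euclidean", "cosine"))
  structure(
    list(table_path = table_path, mode = mode, arch = arch,
         k = as.integer(k), n_hidden = as.integer(n_hidden),
         heads = as.integer(heads), dropout = dropout, metric = metric,
         symmetrized = isTRUE(symmetrized), lr = lr,
         weight_decay = weight_decay, epochs = as.integer(epochs),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @param ... Overrides applied after the file is read.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path)) abort_config(sprintf("no such config file: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Run the full pipeline
#'
#' Executes load -> segment-average -> build-graph -> train -> evaluate
#' and (when `out_dir` is set) writes three text artifacts: the edge list
#' (`graph.tsv`), a JSON model checkpoint (`checkpoint.json`) and a JSON
#' report (`report.json`) embedding the effective config, seed,
#' parameter count and accuracies.
#'
#' @param config A [run_config()].
#' @param table Optional embedding table (otherwise read from
#'   `config$table_path`).
#' @return The report, invisibly, as a named list.
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(table)) {
    if (is.null(config$table_path)) {
      abort_config("either a table or config$table_path is required")
    }
    table <- load_embedding_table(config$table_path)
  }
  table <- collapse_segments(table)

  mode <- config$mode
  if (mode == "auto") mode <- if ("fold" %in% names(table)) "cv" else "holdout"
  if (mode == "cv" && !"fold" %in% names(table)) {
    abort_data("cv mode needs a table with fold assignments")
  }

  tc <- train_config(lr = config$lr, weight_decay = config$weight_decay,
                     epochs = config$epochs, seed = config$seed)

  config_echo <- unclass(config)
  report <- list(config = config_echo, mode = mode)

  if (mode == "cv") {
    cv <- cross_validate(table, config$arch, k = config$k,
                         n_hidden = config$n_hidden, heads = config$heads,
                         metric = config$metric,
                         symmetrized = config$symmetrized, config = tc,
                         dropout = config$dropout)
    report$per_fold_accuracy <- cv$per_fold$accuracy
    report$n_test_per_fold <- cv$per_fold$n_test
    report$mean_accuracy <- cv$mean
    report$sd_accuracy <- cv$std
    report$n_parameters <- cv$n_parameters
    result <- cv
    fit <- NULL
  } else {
    ho <- evaluate_holdout(table, config$arch, k = config$k,
                           n_hidden = config$n_hidden, heads = config$heads,
                           metric = config$metric,
                           symmetrized = config$symmetrized, config = tc,
                           dropout = config$dropout)
    report$test_accuracy <- ho$accuracy
    report$n_test <- sum(ho$masks$test)
    report$n_parameters <- ho$n_parameters
    report$final_train_loss <- tail(ho$fit$loss_history, 1)
    result <- ho
    fit <- ho$fit
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    graph <- knn_graph(table, k = config$k, metric = config$metric,
                       symmetrized = config$symmetrized)
    write_edge_list(graph, file.path(config$out_dir, "graph.tsv"))
    if (!is.null(fit)) {
      write_checkpoint(fit$model, file.path(config$out_dir, "checkpoint.json"))
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  attr(report, "result") <- result
  invisible(report)
}
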