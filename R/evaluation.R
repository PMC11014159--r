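#' Classification accuracy on a node subset
#'
#' @param predictions Either a probability/logit matrix (rows = nodes) or
#'   a vector of 0-based predicted labels.
#' @param truth 0-based true labels.
#' @param mask Logical or integer subset of nodes to score (default all).
#' @return Fraction of mask nodes predicted correctly.
#' @export
accuracy <- function(predictions, truth, mask = NULL) {
  pred <- if (is.matrix(predictions)) predicted_labels(predictions) else as.integer(predictions)
  if (length(pred) != length(truth)) abort_data("predictions/truth length mismatch")
  idx <- if (is.null(mask)) seq_along(truth)
         else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0) abort_config("accuracy over an empty mask is undefined")
  mean(pred[idx] == truth[idx])
}

#' Stratified train/test holdout split
#'
#' Samples `test_fraction` of each class (largest-remainder allocation,
#' so test class proportions match the global ones within one node per
#' class) into the test set, reproducibly by seed.
#'
#' @param table An embedding table.
#' @param test_fraction Test proportion in (0, 1); 0.2 gives the usual
#'   80/20 protocol.
#' @param seed Integer seed for the within-class draws.
#' @return List of logical vectors `train` and `test`.
#' @export
holdout_split <- function(table, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort_config("test_fraction must lie in (0, 1)")
  }
  y <- node_labels(table)
  n <- length(y)
  counts <- tabulate(y + 1L, nbins = n_classes(table))
  if (any(counts < 2L)) abort_data("every class needs at least 2 nodes to split")
  n_test <- allocate_counts(round(test_fraction * n), counts / n)
  set.seed(seed)
  test <- logical(n)
  for (c in seq_along(counts)) {
    ix <- which(y == c - 1L)
    n_c <- max(1L, min(n_test[c], length(ix) - 1L))
    test[sample(ix, n_c)] <- TRUE
  }
  list(train = !test, test = test)
}

#' Cross-validate a GNN over predefined folds
#'
#' Follows the predefined-fold protocol: one k-NN graph is built over all
#' nodes (transductive — test nodes contribute features and edges, never
#' labels), then for each fold f the model is trained from scratch on all
#' nodes outside f and scored on f. Reported as per-fold accuracies with
#' their mean and population standard deviation.
#'
#' @param table An embedding table with a `fold` column.
#' @param arch `"gcn"`, `"sage"` or `"gat"`.
#' @param k Neighbour count for the graph.
#' @param n_hidden Hidden width (per head for GAT).
#' @param heads GAT heads (ignored otherwise).
#' @param metric Distance metric for the graph.
#' @param symmetrized Symmetrize the k-NN digraph (default).
#' @param config A [train_config()]; fold runs use seeds
#'   `config$seed + fold - 1`.
#' @param dropout Dropout probability.
#' @return A `gnn_cv` object; see [tidy()], [glance()], [autoplot()].
#' @examples
#' tbl <- generate_embeddings(synthetic_spec(120, d = 8, n_classes = 3,
#'                                           class_sep = 10, n_folds = 4))
#' cv <- cross_validate(tbl, "gcn", k = 5, n_hidden = 16,
#'                      config = train_config(epochs = 60))
#' glance(cv)
#' @export
cross_validate <- function(table, arch, k, n_hidden, heads = 10L,
                           metric = "euclidean", symmetrized = TRUE,
                           config = train_config(), dropout = 0.5) {
  if (!"fold" %in% names(table)) abort_data("table has no fold assignments")
  folds <- sort(unique(table$fold))
  y <- node_labels(table)
  graph <- knn_graph(table, k = k, metric = metric, symmetrized = symmetrized)
  spec <- model_spec(arch, d_in = n_features(table), n_hidden = n_hidden,
                     n_classes = n_classes(table), heads = heads,
                     dropout = dropout)
  model <- build_model(spec, seed = config$seed)

  per_fold <- purrr::map_dfr(folds, function(f) {
    test_mask <- table$fold == f
    fold_config <- config
    fold_config$seed <- config$seed + f - 1L
    fit <- train(model, graph, table, train_mask = !test_mask,
                 config = fold_config)
    probs <- predict(fit, graph, table)
    tibble::tibble(
      fold = f,
      n_test = sum(test_mask),
      accuracy = accuracy(probs, y, test_mask)
    )
  })

  structure(
    list(
      per_fold = per_fold,
      mean = mean(per_fold$accuracy),
      # population standard deviation across folds (ddof = 0)
      std = sqrt(mean((per_fold$accuracy - mean(per_fold$accuracy))^2)),
      arch = arch, k = k, n_hidden = n_hidden, heads = heads,
      metric = metric, symmetrized = symmetrized, config = config,
      n_parameters = count_parameters(spec)
    ),
    class = "gnn_cv"
  )
}

#' @export
print.gnn_cv <- function(x, ...) {
  cat(sprintf(
    "# %d-fold CV, %s (k = %d, n_hidden = %d): accuracy %.2f ± %.2f\n",
    nrow(x$per_fold), toupper(x$arch), x$k, x$n_hidden, x$mean, x$std
  ))
  invisible(x)
}

#' @method tidy gnn_cv
#' @export
tidy.gnn_cv <- function(x, ...) x$per_fold

#' @method glance gnn_cv
#' @export
glance.gnn_cv <- function(x, ...) {
  tibble::tibble(
    arch = x$arch, k = x$k, n_hidden = x$n_hidden,
    n_folds = nrow(x$per_fold), mean_accuracy = x$mean, sd_accuracy = x$std,
    n_parameters = x$n_parameters
  )
}

#' Per-fold accuracy plot
#'
#' @param object A `gnn_cv`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gnn_cv
#' @export
autoplot.gnn_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(factor(.data$fold), .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "fold", y = "test accuracy") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Train on the train split and score the test split
#'
#' The holdout protocol: one transductive graph over all nodes, training
#' restricted to the train mask, accuracy reported on the test mask.
#'
#' @inheritParams cross_validate
#' @param masks Optional list with logical `train`/`test` (defaults to
#'   the table's `split` column, or a fresh [holdout_split()]).
#' @return A `gnn_holdout` list: `accuracy`, the fitted `gnn_trained`,
#'   the graph, masks and config echo.
#' @export
evaluate_holdout <- function(table, arch, k, n_hidden, heads = 10L,
                             metric = "euclidean", symmetrized = TRUE,
                             config = train_config(), dropout = 0.5,
                             masks = NULL) {
  if (is.null(masks)) {
    if ("split" %in% names(table)) {
      masks <- list(train = table$split == "train", test = table$split == "test")
    } else {
      masks <- holdout_split(table, seed = config$seed)
    }
  }
  y <- node_labels(table)
  graph <- knn_graph(table, k = k, metric = metric, symmetrized = symmetrized)
  spec <- model_spec(arch, d_in = n_features(table), n_hidden = n_hidden,
                     n_classes = n_classes(table), heads = heads,
                     dropout = dropout)
  fit <- train(build_model(spec, seed = config$seed), graph, table,
               train_mask = masks$train, config = config)
  probs <- predict(fit, graph, table)
  structure(
    list(
      accuracy = accuracy(probs, y, masks$test),
      fit = fit, graph = graph, masks = masks,
      arch = arch, k = k, n_hidden = n_hidden, config = config,
      n_parameters = count_parameters(fit$model)
    ),
    class = "gnn_holdout"
  )
}

#' @export
print.gnn_holdout <- function(x, ...) {
  cat(sprintf(
    "# holdout evaluation, %s (k = %d, n_hidden = %d): accuracy %.2f on %d test nodes\n",
    toupper(x$arch), x$k, x$n_hidden, x$accuracy, sum(x$masks$test)
  ))
  invisible(x)
}

#' @method glance gnn_holdout
#' @export
glance.gnn_holdout <- function(x, ...) {
  tibble::tibble(
    arch = x$arch, k = x$k, n_hidden = x$n_hidden,
    accuracy = x$accuracy, n_test = sum(x$masks$test),
    n_parameters = x$n_parameters
  )
}
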