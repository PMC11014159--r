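#' Hyperparameter search space
#'
#' The two architecture-level knobs tuned per model are the graph
#' neighbour count `k` and the hidden width `n_hidden`; learning rate,
#' weight decay, dropout and the epoch budget stay fixed by the training
#' protocol. Default ranges bracket the optima reported for deep-audio
#' embedding corpora (k between 4 and 12, hidden widths between 40 and
#' 252).
#'
#' @param k_range Integer interval `c(lo, hi)` for the neighbour count.
#' @param hidden_range Integer interval for the hidden width.
#' @param n_trials Number of sampled configurations.
#' @param seed Integer seed making the whole search deterministic.
#' @return A `search_space` list.
#' @export
search_space <- function(k_range = c(3L, 15L), hidden_range = c(32L, 256L),
                         n_trials = 20L, seed = 1L) {
  if (k_range[2] < k_range[1] || hidden_range[2] < hidden_range[1]) {
    abort_config("search ranges must be nonempty")
  }
  if (n_trials < 1) abort_config("n_trials must be >= 1")
  structure(
    list(k_range = as.integer(k_range), hidden_range = as.integer(hidden_range),
         n_trials = as.integer(n_trials), seed = as.integer(seed)),
    class = "search_space"
  )
}

#' Random search over k and hidden width
#'
#' Samples `n_trials` configurations uniformly from the space and scores
#' each by accuracy on an inner validation split carved out of the
#' training nodes only: test-mask nodes join every trial's graph (the
#' setting is transductive) but their labels are never read by the
#' objective. Scoring on the test labels themselves leaks the benchmark
#' into model selection, so it must be requested explicitly via
#' `objective = "test"`.
#'
#' @param table An embedding table.
#' @param arch `"gcn"`, `"sage"` or `"gat"`.
#' @param space A [search_space()].
#' @param config A [train_config()] used for every trial.
#' @param test_mask Logical vector of nodes excluded from the objective
#'   (default: the table's `split == "test"` nodes, if any).
#' @param val_fraction Fraction of training nodes held out as the inner
#'   validation set.
#' @param heads,metric,dropout Passed through to the trial models.
#' @param objective `"validation"` (default) or `"test"` (explicit
#'   opt-in; scores trials on the test mask).
#' @return A `gnn_hpo` object with `best` (k, n_hidden, score) and the
#'   full trial log; see `tidy()`/`glance()`.
#' @export
hpo_search <- function(table, arch, space = search_space(),
                       config = train_config(), test_mask = NULL,
                       val_fraction = 0.2, heads = 10L,
                       metric = "euclidean", dropout = 0.5,
                       objective = c("validation", "test")) {
  objective <- match.arg(objective)
  y <- node_labels(table)
  n <- nrow(table)
  if (is.null(test_mask)) {
    test_mask <- if ("split" %in% names(table)) table$split == "test" else rep(FALSE, n)
  }
  if (objective == "test" && !any(test_mask)) {
    abort_config("objective = \"test\" needs a nonempty test mask")
  }
  if (space$k_range[2] >= n) abort_config("k_range exceeds n_nodes - 1")

  pool <- which(!test_mask) # nodes whose labels the objective may read
  set.seed(space$seed)
  sample_range <- function(lo, hi, n) {
    # robust to collapsed ranges (sample() would expand a scalar to 1:x)
    seq.int(lo, hi)[sample.int(hi - lo + 1L, n, replace = TRUE)]
  }
  ks <- sample_range(space$k_range[1], space$k_range[2], space$n_trials)
  hiddens <- sample_range(space$hidden_range[1], space$hidden_range[2],
                          space$n_trials)

  if (objective == "validation") {
    # stratified inner split of the training pool
    y_pool <- y[pool]
    counts <- tabulate(y_pool + 1L, nbins = n_classes(table))
    n_val <- allocate_counts(round(val_fraction * length(pool)),
                             counts / length(pool))
    val <- logical(n)
    for (c in seq_along(counts)) {
      ix <- pool[y_pool == c - 1L]
      val[sample(ix, max(1L, min(n_val[c], length(ix) - 1L)))] <- TRUE
    }
    inner_train <- !test_mask & !val
    score_mask <- val
  } else {
    inner_train <- !test_mask
    score_mask <- test_mask
  }

  trials <- purrr::map_dfr(seq_len(space$n_trials), function(i) {
    graph <- knn_graph(table, k = ks[i], metric = metric)
    spec <- model_spec(arch, d_in = n_features(table), n_hidden = hiddens[i],
                       n_classes = n_classes(table), heads = heads,
                       dropout = dropout)
    trial_config <- config
    trial_config$seed <- config$seed + i - 1L
    fit <- train(build_model(spec, seed = trial_config$seed), graph, table,
                 train_mask = inner_train, config = trial_config)
    probs <- predict(fit, graph, table)
    tibble::tibble(
      trial = i, k = ks[i], n_hidden = hiddens[i],
      score = accuracy(probs, y, score_mask)
    )
  })

  best_row <- trials[which.max(trials$score), ]
  structure(
    list(
      best = list(k = best_row$k, n_hidden = best_row$n_hidden,
                  score = best_row$score),
      trials = trials, arch = arch, space = space, objective = objective,
      config = config
    ),
    class = "gnn_hpo"
  )
}

#' @export
print.gnn_hpo <- function(x, ...) {
  cat(sprintf(
    "# hyperparameter search, %s: best k = %d, n_hidden = %d (%s accuracy %.3f over %d trials)\n",
    toupper(x$arch), x$best$k, x$best$n_hidden, x$objective, x$best$score,
    nrow(x$trials)
  ))
  invisible(x)
}

#' @method tidy gnn_hpo
#' @export
tidy.gnn_hpo <- function(x, ...) x$trials

#' @method glance gnn_hpo
#' @export
glance.gnn_hpo <- function(x, ...) {
  tibble::tibble(
    arch = x$arch, best_k = x$best$k, best_n_hidden = x$best$n_hidden,
    best_score = x$best$score, n_trials = nrow(x$trials),
    objective = x$objective
  )
}

#' Published best hyperparameters for deep-audio embedding corpora
#'
#' Presets pairing each embedding family (128-d VGGish-style, 1024-d
#' YAMNet-style, 2048-d PANNs-style) and architecture with the tuned
#' neighbour count and hidden width for the two reference protocols:
#' ten-fold urban-sound classification (`"urban10"`) and the land-cover
#' holdout corpus (`"landcover"`). These are starting points, not
#' regenerable targets — the tuning objective behind them is not part of
#' the protocol.
#'
#' @param protocol `"urban10"` or `"landcover"`.
#' @return Tibble with `features`, `d_in`, `arch`, `k`, `n_hidden`.
#' @export
hyperparameter_presets <- function(protocol = c("urban10", "landcover")) {
  protocol <- match.arg(protocol)
  if (protocol == "urban10") {
    tibble::tribble(
      ~features, ~d_in, ~arch, ~k, ~n_hidden,
      "vggish", 128L, "gcn", 10L, 55L,
      "vggish", 128L, "sage", 12L, 57L,
      "vggish", 128L, "gat", 9L, 52L,
      "yamnet", 1024L, "gcn", 5L, 196L,
      "yamnet", 1024L, "sage", 11L, 55L,
      "yamnet", 1024L, "gat", 6L, 252L,
      "panns", 2048L, "gcn", 4L, 40L,
      "panns", 2048L, "sage", 5L, 183L,
      "panns", 2048L, "gat", 10L, 206L
    )
  } else {
    tibble::tribble(
      ~features, ~d_in, ~arch, ~k, ~n_hidden,
      "vggish", 128L, "gcn", 5L, 48L,
      "vggish", 128L, "sage", 10L, 63L,
      "vggish", 128L, "gat", 6L, 49L,
      "yamnet", 1024L, "gcn", 5L, 62L,
      "yamnet", 1024L, "sage", 6L, 56L,
      "yamnet", 1024L, "gat", 6L, 53L,
      "panns", 2048L, "gcn", 6L, 64L,
      "panns", 2048L, "sage", 7L, 63L,
      "panns", 2048L, "gat", 5L, 51L
    )
  }
}
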