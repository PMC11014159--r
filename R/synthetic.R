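#' Specify a synthetic embedding table
#'
#' The generator emulates the statistical structure the pipeline assumes
#' of deep audio embeddings: each class is an isotropic Gaussian cluster
#' in d dimensions, with class means placed at scaled simplex vertices so
#' every pair of means is exactly `class_sep * noise_sd` apart. Fold or
#' train/test assignments are stratified and deterministic, mimicking
#' either ten predefined folds or an 80/20 holdout.
#'
#' `class_sep` is therefore the single interpretable separation knob,
#' measured in units of the within-class noise standard deviation: 0 means
#' labels carry no signal, and by ~8 a 1-nearest-neighbour classifier is
#' essentially perfect.
#'
#' @param n_nodes Number of recordings (nodes).
#' @param d Embedding dimension (128 for VGGish-style, 1024 YAMNet-style,
#'   2048 PANNs-style; anything >= `n_classes` works).
#' @param n_classes Number of classes C.
#' @param class_sep Distance between every pair of class means, in units
#'   of `noise_sd`. Must be >= 0.
#' @param noise_sd Within-class standard deviation per dimension (> 0).
#' @param class_proportions C nonnegative reals summing to 1; class counts
#'   are allocated by largest remainder so they total `n_nodes` exactly.
#' @param n_folds Number of folds (>= 2) for a predefined-fold table, or
#'   `NULL` to use `holdout_fraction` instead.
#' @param holdout_fraction Test fraction in (0, 1) for a train/test table;
#'   ignored when `n_folds` is given.
#' @param seed Integer seed; identical seeds reproduce the table bit for
#'   bit on the same platform.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes, d, n_classes,
                           class_sep = 4, noise_sd = 1,
                           class_proportions = rep(1 / n_classes, n_classes),
                           n_folds = NULL, holdout_fraction = 0.2,
                           seed = 1L) {
  if (n_classes < 1L) abort_config("need at least one class")
  if (n_nodes < n_classes) abort_config("n_nodes must be >= n_classes")
  if (d < 1L) abort_config("d must be positive")
  if (class_sep < 0) abort_config("class_sep must be nonnegative")
  if (noise_sd <= 0) abort_config("noise_sd must be positive")
  if (length(class_proportions) != n_classes ||
    any(class_proportions < 0) ||
    abs(sum(class_proportions) - 1) > 1e-9) {
    abort_config("class_proportions must be C nonnegative reals summing to 1")
  }
  if (is.null(n_folds)) {
    if (holdout_fraction <= 0 || holdout_fraction >= 1) {
      abort_config("holdout_fraction must lie in (0, 1)")
    }
  } else if (n_folds < 2L) {
    abort_config("n_folds must be >= 2")
  }
  if (class_sep > 0 && d < n_classes) {
    abort_config("d must be >= n_classes to place equidistant class means")
  }
  structure(
    list(
      n_nodes = as.integer(n_nodes), d = as.integer(d),
      n_classes = as.integer(n_classes), class_sep = class_sep,
      noise_sd = noise_sd, class_proportions = class_proportions,
      n_folds = if (is.null(n_folds)) NULL else as.integer(n_folds),
      holdout_fraction = holdout_fraction, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Largest-remainder allocation of n items to proportions p (sums to n).
allocate_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# C equidistant mean vectors in R^d with pairwise distance `sep`:
# scaled, centred simplex vertices in the first C coordinates.
simplex_means <- function(C, d, sep) {
  M <- matrix(0, C, d)
  if (sep > 0) {
    V <- diag(C) * sep / sqrt(2)
    V <- sweep(V, 2, colMeans(V)) # centre at the origin
    M[, seq_len(C)] <- V
  }
  M
}

#' Generate a synthetic embedding table
#'
#' Draws class-conditional Gaussian features per [synthetic_spec()],
#' assigns labels by largest-remainder class counts, and deals folds (or
#' the train/test split) deterministically within each class so that every
#' fold's class mix matches the global mix to within one node per class.
#'
#' @param spec A [synthetic_spec()].
#' @return An [as_embedding_table()] tibble.
#' @examples
#' tbl <- generate_embeddings(synthetic_spec(60, d = 8, n_classes = 3,
#'                                           class_sep = 6, n_folds = 5))
#' table(node_labels(tbl), tbl$fold)
#' @export
generate_embeddings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  counts <- allocate_counts(spec$n_nodes, spec$class_proportions)
  if (any(counts == 0L)) {
    abort_config("a class received zero nodes; increase n_nodes")
  }
  labels <- rep.int(seq_len(spec$n_classes) - 1L, counts)
  means <- simplex_means(spec$n_classes, spec$d, spec$class_sep * spec$noise_sd)
  feats <- means[labels + 1L, , drop = FALSE] +
    matrix(
      rnorm(spec$n_nodes * spec$d, sd = spec$noise_sd),
      spec$n_nodes, spec$d
    )

  # deterministic stratified assignment: within each class, deal nodes
  # round-robin across folds (or mark a trailing stratum as test)
  if (!is.null(spec$n_folds)) {
    assign_col <- integer(spec$n_nodes)
    for (c in seq_len(spec$n_classes) - 1L) {
      ix <- which(labels == c)
      assign_col[ix] <- ((seq_along(ix) - 1L) %% spec$n_folds) + 1L
    }
    split_df <- tibble::tibble(fold = assign_col)
  } else {
    tag <- rep("train", spec$n_nodes)
    n_test_per_class <- allocate_counts(
      round(spec$holdout_fraction * spec$n_nodes),
      counts / spec$n_nodes
    )
    for (c in seq_len(spec$n_classes) - 1L) {
      ix <- which(labels == c)
      n_test <- min(n_test_per_class[c + 1L], length(ix) - 1L)
      if (n_test > 0) tag[tail(ix, n_test)] <- "test"
    }
    split_df <- tibble::tibble(split = tag)
  }

  width <- nchar(as.character(spec$n_nodes))
  df <- tibble::tibble(
    id = sprintf(paste0("node-%0", width, "d"), seq_len(spec$n_nodes)),
    label = sprintf("class-%02d", labels)
  )
  df <- dplyr::bind_cols(df, split_df)
  feat_df <- tibble::as_tibble(as.data.frame(feats))
  names(feat_df) <- paste0("f", seq_len(spec$d) - 1L)
  as_embedding_table(dplyr::bind_cols(df, feat_df))
}

#' Land-cover class proportions preset
#'
#' The class mix of a large passive-acoustic-monitoring campaign over a
#' tropical savanna reserve: 14,546 forest, 14,994 savanna and 41,957
#' pasture recordings (roughly 20/21/59%). Useful as
#' `class_proportions` for imbalanced fixtures scaled to any `n_nodes`.
#'
#' @return Named numeric vector of three proportions summing to 1.
#' @export
landcover_proportions <- function() {
  counts <- c(forest = 14546, savanna = 14994, pasture = 41957)
  counts / sum(counts)
}
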