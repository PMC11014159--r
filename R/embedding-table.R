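#' Embedding tables
#'
#' An embedding table is the node payload of the audio graph: one row per
#' recording, a fixed-length real feature vector (the deep embedding), an
#' integer class label, and either a predefined fold index (1..F, the
#' UrbanSound8K convention) or a `train`/`test` split tag. It is stored as
#' a tibble with columns `id`, `label`, one of `fold`/`split`, and feature
#' columns `f0..f{d-1}`, plus a `class_names` attribute recording the
#' mapping from dense integer labels (0-based) back to original names.
#'
#' @param x A data frame with columns `id`, `label`, optionally `fold` or
#'   `split`, and numeric feature columns `f0`, `f1`, ...
#' @param class_names Optional character vector fixing the label encoding;
#'   by default the sorted unique labels present.
#' @return A tibble of class `embedding_table`.
#' @examples
#' tbl <- tibble::tibble(
#'   id = c("a", "b", "c"), label = c("dog_bark", "siren", "dog_bark"),
#'   fold = c(1L, 1L, 2L), f0 = c(0, 1, 0.2), f1 = c(0, 0, 0.1)
#' )
#' as_embedding_table(tbl)
#' @export
as_embedding_table <- function(x, class_names = NULL) {
  x <- tibble::as_tibble(x)
  if (!"id" %in% names(x)) abort_data("embedding table needs an `id` column")
  if (!"label" %in% names(x)) abort_data("embedding table needs a `label` column")
  feat_cols <- grep("^f[0-9]+$", names(x), value = TRUE)
  if (length(feat_cols) == 0L) {
    abort_data("embedding table needs feature columns named f0, f1, ...")
  }
  # canonical feature order f0..f{d-1}
  feat_cols <- feat_cols[order(as.integer(sub("^f", "", feat_cols)))]
  expected <- paste0("f", seq_along(feat_cols) - 1L)
  if (!identical(feat_cols, expected)) {
    abort_data("feature columns must form a contiguous range f0..f{d-1}")
  }

  for (fc in feat_cols) {
    v <- x[[fc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort_data(sprintf(
        "non-numeric feature value in column `%s`, row %d", fc,
        if (is.na(bad)) 1L else bad
      ))
    }
    if (anyNA(v)) {
      abort_data(sprintf(
        "missing feature value in column `%s`, row %d", fc, which(is.na(v))[1]
      ))
    }
  }

  has_fold <- "fold" %in% names(x)
  has_split <- "split" %in% names(x)
  if (has_fold && has_split) {
    abort_data("embedding table must have `fold` or `split`, not both")
  }
  if (has_fold) {
    f <- x$fold
    if (anyNA(f) || !all(f == as.integer(f))) {
      abort_data("`fold` must be integer with no missing values")
    }
    x$fold <- as.integer(f)
    fu <- sort(unique(x$fold))
    if (!identical(fu, seq.int(min(fu), max(fu))) || min(fu) < 1L) {
      abort_data("fold indices must form a contiguous range starting at 1")
    }
  }
  if (has_split) {
    if (!all(x$split %in% c("train", "test"))) {
      abort_data("`split` values must be \"train\" or \"test\"")
    }
  }

  if (is.null(class_names)) {
    class_names <- attr(x, "class_names", exact = TRUE)
  }
  lab <- x$label
  if (is.null(class_names)) {
    # dense re-encoding in lexicographic order of the observed names;
    # NA labels (unlabeled test rows) are preserved as NA
    class_names <- sort(unique(as.character(lab[!is.na(lab)])))
  }
  enc <- match(as.character(lab), class_names) - 1L
  if (any(!is.na(lab) & is.na(enc))) {
    # allow unknown labels only on test rows (they are never trained on)
    unknown <- !is.na(lab) & is.na(enc)
    if (!has_split || any(x$split[unknown] != "test")) {
      abort_data("unknown class label outside the test split")
    }
  }
  x$label <- enc

  x <- x[c("id", "label", if (has_fold) "fold", if (has_split) "split", feat_cols)]
  attr(x, "class_names") <- class_names
  class(x) <- c("embedding_table", class(tibble::tibble()))
  validate_embedding_table(x)
}

validate_embedding_table <- function(x) {
  # duplicated ids are legal: they represent per-segment rows of one
  # recording and are merged by collapse_segments() before graph building
  cn <- attr(x, "class_names", exact = TRUE)
  if (any(!is.na(x$label) & (x$label < 0L | x$label >= length(cn)))) {
    abort_data("encoded labels out of range")
  }
  x
}

#' @export
print.embedding_table <- function(x, ...) {
  cn <- attr(x, "class_names", exact = TRUE)
  cat(sprintf(
    "# An embedding table: %d nodes x %d features, %d classes\n",
    nrow(x), n_features(x), length(cn)
  ))
  NextMethod()
}

#' Accessors for embedding tables
#'
#' `feature_matrix()` returns the n x d numeric matrix of node features
#' (rows in table order, named by node id); `node_labels()` the 0-based
#' integer labels; `class_names()` the label decoding; `n_features()` and
#' `n_classes()` the dimensions.
#'
#' @param table An [as_embedding_table()] object.
#' @return See individual descriptions.
#' @export
feature_matrix <- function(table) {
  feat_cols <- grep("^f[0-9]+$", names(table), value = TRUE)
  m <- as.matrix(table[feat_cols])
  rownames(m) <- table$id
  m
}

#' @rdname feature_matrix
#' @export
node_labels <- function(table) table$label

#' @rdname feature_matrix
#' @export
class_names <- function(table) attr(table, "class_names", exact = TRUE)

#' @rdname feature_matrix
#' @export
n_features <- function(table) sum(grepl("^f[0-9]+$", names(table)))

#' @rdname feature_matrix
#' @export
n_classes <- function(table) length(class_names(table))

table_delim <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read and write embedding tables
#'
#' The on-disk format is delimited text (comma for `.csv`, tab for
#' `.tsv`/`.txt`) with header `id,label[,fold|split],f0..f{d-1}`. Labels
#' are written as their original class names and re-encoded to dense
#' 0-based integers on load; writing then loading reproduces the table
#' exactly.
#'
#' @param path Path to a delimited text file.
#' @param class_names Optional fixed label encoding (see
#'   [as_embedding_table()]).
#' @return `load_embedding_table()` returns an `embedding_table`;
#'   `write_embedding_table()` returns `path` invisibly.
#' @export
load_embedding_table <- function(path, class_names = NULL) {
  if (!file.exists(path)) abort_data(sprintf("no such file: %s", path))
  raw <- readr::read_delim(
    path,
    delim = table_delim(path), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  feat_cols <- grep("^f[0-9]+$", names(raw), value = TRUE)
  for (fc in feat_cols) {
    if (is.character(raw[[fc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[fc]]))) |
        toupper(raw[[fc]]) %in% c("NA", "NAN"))[1]
      abort_data(sprintf(
        "non-numeric feature value in column `%s`, row %d of %s",
        fc, if (is.na(bad)) 1L else bad, path
      ))
    }
  }
  as_embedding_table(raw, class_names = class_names)
}

#' @rdname load_embedding_table
#' @param table An embedding table.
#' @export
write_embedding_table <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  out <- tibble::as_tibble(table)
  cn <- class_names(table)
  out$label <- cn[out$label + 1L]
  readr::write_delim(out, path, delim = table_delim(path), progress = FALSE)
  invisible(path)
}

#' Average per-segment embeddings into one vector
#'
#' Segment-level extractors emit one embedding per ~1 s window (VGGish:
#' 128-d per 0.96 s; YAMNet: 1024-d per 0.48 s hop). A clip-level node
#' embedding is the column-wise arithmetic mean of its segment rows.
#'
#' @param segments Numeric matrix, one row per segment.
#' @return Numeric vector of length `ncol(segments)`.
#' @examples
#' average_segments(rbind(c(1, 2), c(3, 4))) # c(2, 3)
#' @export
average_segments <- function(segments) {
  segments <- as.matrix(segments)
  if (nrow(segments) < 1L) abort_data("average_segments: empty segment matrix")
  if (anyNA(segments)) abort_data("average_segments: missing values")
  colMeans(segments)
}

#' Collapse multiple segment rows per recording into one row
#'
#' Rows of `table` sharing an `id` are treated as segments of one
#' recording and averaged with [average_segments()]; label and fold/split
#' must agree within an id. Clip-level tables (unique ids) pass through
#' unchanged.
#'
#' @param table An embedding table, possibly with repeated ids.
#' @return An embedding table with unique ids, in first-appearance order.
#' @export
collapse_segments <- function(table) {
  stopifnot(inherits(table, "embedding_table"))
  if (!anyDuplicated(table$id)) return(table)
  feat_cols <- grep("^f[0-9]+$", names(table), value = TRUE)
  meta_cols <- intersect(c("label", "fold", "split"), names(table))
  grouped <- dplyr::group_by(tibble::as_tibble(table), .data$id)
  for (mc in meta_cols) {
    n_distinct_meta <- dplyr::summarise(
      grouped,
      n = dplyr::n_distinct(.data[[mc]]), .groups = "drop"
    )
    if (any(n_distinct_meta$n > 1L)) {
      abort_data(sprintf("segments of one recording disagree on `%s`", mc))
    }
  }
  out <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(meta_cols), dplyr::first),
    dplyr::across(dplyr::all_of(feat_cols), mean),
    .groups = "drop"
  )
  out <- out[match(unique(table$id), out$id), ]
  out$label <- class_names(table)[out$label + 1L]
  as_embedding_table(out, class_names = class_names(table))
}

#' Principal-component view of an embedding table
#'
#' Projects the node features onto their first two principal components,
#' coloured by class — a quick check of how separable the embedding space
#' is before any graph is built.
#'
#' @param object An embedding table.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot embedding_table
#' @export
autoplot.embedding_table <- function(object, ...) {
  pcs <- prcomp(feature_matrix(object), rank. = 2)$x
  df <- tibble::tibble(
    PC1 = pcs[, 1], PC2 = pcs[, 2],
    class = factor(class_names(object)[object$label + 1L])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "class") +
    ggplot2::theme_minimal()
}
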