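#' Specify a two-layer GNN
#'
#' All three architectures share the same template: two message-passing
#' layers with ReLU in between, dropout (default 0.5) on each layer's
#' input during training, and raw class logits out of layer 2 (softmax
#' lives in the loss). The hidden width is per head for GAT, whose first
#' layer concatenates `heads` attention heads (default 10) and whose
#' second layer uses a single head.
#'
#' @param arch `"gcn"`, `"sage"` or `"gat"`.
#' @param d_in Input embedding dimension (e.g. 128 VGGish-style, 1024
#'   YAMNet-style, 2048 PANNs-style).
#' @param n_hidden Hidden width (per head for GAT).
#' @param n_classes Output dimension C.
#' @param heads Attention heads in the GAT hidden layer.
#' @param dropout Dropout probability on layer inputs during training.
#' @return A `model_spec` list.
#' @export
model_spec <- function(arch = c("gcn", "sage", "gat"), d_in, n_hidden,
                       n_classes, heads = 10L, dropout = 0.5) {
  arch <- match.arg(tolower(arch), c("gcn", "sage", "gat"))
  if (d_in < 1 || n_hidden < 1 || n_classes < 2) {
    abort_config("need d_in >= 1, n_hidden >= 1, n_classes >= 2")
  }
  if (heads < 1) abort_config("heads must be >= 1")
  if (dropout < 0 || dropout >= 1) abort_config("dropout must lie in [0, 1)")
  structure(
    list(
      arch = arch, d_in = as.integer(d_in), n_hidden = as.integer(n_hidden),
      n_classes = as.integer(n_classes),
      heads = if (arch == "gat") as.integer(heads) else 1L,
      dropout = dropout
    ),
    class = "model_spec"
  )
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

init_gcn_layer <- function(d_in, d_out) {
  gcn_layer_params(glorot(d_in, d_out), numeric(d_out))
}

init_sage_layer <- function(d_in, d_out) {
  sage_layer_params(glorot(d_in, d_out), glorot(d_in, d_out), numeric(d_out))
}

init_gat_layer <- function(d_in, d_head, heads) {
  Fdim <- heads * d_head
  sa <- sqrt(6 / (Fdim + 1))
  gat_layer_params(
    W_l = glorot(d_in, Fdim), W_r = glorot(d_in, Fdim),
    a = runif(Fdim, -sa, sa),
    out_bias = numeric(Fdim),
    heads = heads
  )
}

#' Build an initialised two-layer GNN
#'
#' Weights use uniform Glorot (fan-based) initialisation; biases start at
#' zero. With a `seed` the initialisation is reproducible.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed for the initialisation draw.
#' @return A `gnn_model` with `spec` and a two-element `layers` list.
#' @examples
#' m <- build_model(model_spec("gcn", d_in = 128, n_hidden = 55,
#'                             n_classes = 10), seed = 1)
#' count_parameters(m)
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  layers <- switch(spec$arch,
    gcn = list(
      init_gcn_layer(spec$d_in, spec$n_hidden),
      init_gcn_layer(spec$n_hidden, spec$n_classes)
    ),
    sage = list(
      init_sage_layer(spec$d_in, spec$n_hidden),
      init_sage_layer(spec$n_hidden, spec$n_classes)
    ),
    gat = list(
      init_gat_layer(spec$d_in, spec$n_hidden, spec$heads),
      # single-head output layer reading the concatenated heads
      init_gat_layer(spec$heads * spec$n_hidden, spec$n_classes, 1L)
    )
  )
  structure(list(spec = spec, layers = layers), class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "# gnn_model: %s, %d -> %d%s -> %d (%s trainable parameters)\n",
    toupper(s$arch), s$d_in, s$n_hidden,
    if (s$arch == "gat") sprintf(" x %d heads", s$heads) else "",
    s$n_classes, format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

# Every numeric leaf of a layer's parameter list is trainable.
layer_param_arrays <- function(layer) {
  keep <- vapply(layer, is.numeric, logical(1))
  nm <- names(layer)[keep]
  nm <- setdiff(nm, c("heads", "d_head", "leaky_slope"))
  layer[nm]
}

#' Count trainable parameters
#'
#' Exact number of scalar weights and biases the optimiser updates:
#' per layer, `d_in * d_out + d_out` for GCN, `2 * d_in * d_out + d_out`
#' for GraphSAGE (neighbour and self transforms, one bias), and for GAT
#' `2 * (d_in * F + F) + F + F` with `F = heads * d_head` (two biased
#' input transforms, the attention vector, the output bias).
#'
#' @param model A [build_model()] result (or a [model_spec()], which is
#'   built with zero-initialised shapes first).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model, seed = 0)
  stopifnot(inherits(model, "gnn_model"))
  sum(vapply(
    model$layers,
    function(layer) sum(lengths(layer_param_arrays(layer))),
    numeric(1)
  ))
}

#' Save and restore model checkpoints
#'
#' Checkpoints are JSON: the model spec plus flat parameter arrays with
#' their shapes. Text-only, diff-able, and exact to full double
#' precision.
#'
#' @param model A `gnn_model`.
#' @param path File path for the JSON checkpoint.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` the restored `gnn_model`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gnn_model"))
  payload <- list(
    format = "audiograph-checkpoint-v1",
    spec = unclass(model$spec),
    layers = lapply(model$layers, function(layer) {
      arrays <- layer_param_arrays(layer)
      lapply(arrays, function(x) {
        list(dim = dim(x) %||% length(x), values = as.numeric(x))
      })
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("no such file: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "audiograph-checkpoint-v1")) {
    abort_data("not an audiograph checkpoint")
  }
  sp <- payload$spec
  spec <- model_spec(sp$arch, sp$d_in, sp$n_hidden, sp$n_classes,
                     heads = sp$heads, dropout = sp$dropout)
  model <- build_model(spec, seed = 0)
  for (li in seq_along(model$layers)) {
    stored <- payload$layers[[li]]
    for (nm in names(stored)) {
      x <- as.numeric(unlist(stored[[nm]]$values))
      dm <- as.integer(unlist(stored[[nm]]$dim))
      model$layers[[li]][[nm]] <-
        if (length(dm) == 2) matrix(x, dm[1], dm[2]) else x
    }
  }
  model
}
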