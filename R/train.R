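#' Training configuration
#'
#' Full-batch transductive training: one gradient step per epoch on the
#' cross-entropy of the training-mask nodes, with the whole graph
#' (including unlabelled test nodes) participating in message passing.
#' Defaults follow the common protocol for this setting: Adam with
#' learning rate 0.001, weight decay 5e-4 applied to every trainable
#' parameter, and a fixed epoch budget (300 for fold-based corpora; 1300
#' is the preset used for the large holdout corpus).
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 coefficient folded into the Adam gradient.
#' @param epochs Number of full-batch epochs (>= 0).
#' @param seed Integer seed controlling initial weights and dropout.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, weight_decay = 5e-4, epochs = 300L,
                         seed = 1L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (lr <= 0) abort_config("lr must be positive")
  if (epochs < 0) abort_config("epochs must be >= 0")
  if (weight_decay < 0) abort_config("weight_decay must be >= 0")
  structure(
    list(lr = lr, weight_decay = weight_decay, epochs = as.integer(epochs),
         seed = as.integer(seed), beta1 = beta1, beta2 = beta2, eps = eps),
    class = "train_config"
  )
}

# Architecture-specific graph operators, computed once per training run.
graph_context <- function(graph, arch) {
  switch(arch,
    gcn = list(S = gcn_propagator(graph)),
    sage = list(M = mean_aggregator(graph)),
    gat = list(ctx = gat_edge_context(graph))
  )
}

# Forward pass through both layers with caches for the backward pass.
# dropout_masks: NULL (evaluation) or list of two 0/1 matrices; inverted
# dropout, so kept units are scaled by 1/(1-p) at train time.
model_forward <- function(model, gctx, H0, dropout_masks = NULL) {
  spec <- model$spec
  p <- spec$dropout
  drop_in <- function(X, mask) {
    if (is.null(mask)) X else X * mask / (1 - p)
  }
  X1 <- drop_in(H0, dropout_masks$m1)
  c1 <- layer_forward(model$layers[[1]], gctx, X1, spec$arch, first = TRUE)
  A1 <- relu(c1$Z)
  X2 <- drop_in(A1, dropout_masks$m2)
  c2 <- layer_forward(model$layers[[2]], gctx, X2, spec$arch, first = FALSE)
  list(logits = c2$Z, X1 = X1, c1 = c1, A1 = A1, X2 = X2, c2 = c2)
}

layer_forward <- function(params, gctx, X, arch, first) {
  switch(arch,
    gcn = {
      P <- as.matrix(gctx$S %*% X)
      list(X = X, P = P, Z = add_bias(P %*% params$W, params$bias))
    },
    sage = {
      MX <- as.matrix(gctx$M %*% X)
      list(X = X, MX = MX,
           Z = add_bias(MX %*% params$W + X %*% params$B, params$bias))
    },
    gat = {
      fw <- gat_forward(X, gctx$ctx, params, concat = first)
      fw$X <- X
      fw
    }
  )
}

# dZ: gradient at the layer's pre-activation output.
# Returns gradients for every parameter array plus dX at the input.
layer_backward <- function(params, gctx, cache, dZ, arch, first) {
  switch(arch,
    gcn = list(
      grads = list(W = crossprod(cache$P, dZ), bias = colSums(dZ)),
      dX = as.matrix(Matrix::crossprod(gctx$S, dZ)) %*% t(params$W)
    ),
    sage = list(
      grads = list(
        W = crossprod(cache$MX, dZ),
        B = crossprod(cache$X, dZ),
        bias = colSums(dZ)
      ),
      dX = as.matrix(Matrix::crossprod(gctx$M, dZ %*% t(params$W))) +
        dZ %*% t(params$B)
    ),
    gat = gat_backward(params, gctx$ctx, cache, dZ, concat = first)
  )
}

gat_backward <- function(params, ctx, cache, dZ, concat) {
  heads <- params$heads
  d_head <- params$d_head
  Fdim <- heads * d_head
  slope <- params$leaky_slope
  hd <- rep(seq_len(heads), each = d_head)
  m <- length(ctx$src)
  out_bias_grad <- colSums(dZ)
  # gradient at the per-head aggregated output O
  if (concat) {
    dO <- dZ
  } else {
    dO <- matrix(0, ctx$n, Fdim)
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * d_head + 1L):(h * d_head)
      dO[, idx] <- dZ / heads
    }
  }

  dOe <- dO[ctx$dst, , drop = FALSE]
  ind <- matrix(0, Fdim, heads) # column-to-head summing operator
  ind[cbind(seq_len(Fdim), hd)] <- 1
  dalpha <- (dOe * cache$Se) %*% ind # m x heads
  # message term: dS[v] += alpha_uv * dO[u]
  dS <- rowsum(dOe * cache$alpha_full, ctx$src, reorder = TRUE)

  # softmax backward within each target's neighbourhood
  sdot <- rowsum(cache$alpha * dalpha, ctx$dst, reorder = TRUE)
  dL <- cache$alpha * (dalpha - sdot[ctx$dst, , drop = FALSE])
  dL_full <- dL[, hd, drop = FALSE]

  da <- colSums(cache$R * dL_full)
  lgrad <- slope + (1 - slope) * cache$pos
  dTm <- dL_full * lgrad * rep(params$a, each = m)
  dG <- rowsum(dTm, ctx$dst, reorder = TRUE)
  dS <- dS + rowsum(dTm, ctx$src, reorder = TRUE)

  X <- cache$X
  list(
    grads = list(
      W_l = crossprod(X, dG), b_l = colSums(dG),
      W_r = crossprod(X, dS), b_r = colSums(dS),
      a = da, out_bias = out_bias_grad
    ),
    dX = dG %*% t(params$W_l) + dS %*% t(params$W_r)
  )
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Cross-entropy over the masked nodes; returns the loss and the gradient
# at the logits (zero outside the mask).
ce_loss <- function(logits, y, mask_idx) {
  P <- softmax_rows(logits[mask_idx, , drop = FALSE])
  picked <- cbind(seq_along(mask_idx), y[mask_idx] + 1L)
  loss <- -mean(log(pmax(P[picked], 1e-300)))
  dP <- P
  dP[picked] <- dP[picked] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[mask_idx, ] <- dP / length(mask_idx)
  list(loss = loss, dlogits = dlogits)
}

# Loss of the model on (graph ctx, features, labels, mask) with dropout
# off — the function the finite-difference gradient check probes.
model_loss <- function(model, gctx, H0, y, mask_idx) {
  fw <- model_forward(model, gctx, H0, dropout_masks = NULL)
  ce_loss(fw$logits, y, mask_idx)$loss
}

model_gradients <- function(model, gctx, H0, y, mask_idx) {
  fw <- model_forward(model, gctx, H0, dropout_masks = NULL)
  cl <- ce_loss(fw$logits, y, mask_idx)
  b2 <- layer_backward(model$layers[[2]], gctx, fw$c2, cl$dlogits,
                       model$spec$arch, first = FALSE)
  dZ1 <- b2$dX * (fw$c1$Z > 0)
  b1 <- layer_backward(model$layers[[1]], gctx, fw$c1, dZ1,
                       model$spec$arch, first = TRUE)
  list(loss = cl$loss, grads = list(b1$grads, b2$grads))
}

flatten_params <- function(model) {
  unlist(lapply(model$layers, function(l) {
    lapply(layer_param_arrays(l), as.numeric)
  }), use.names = FALSE)
}

unflatten_params <- function(model, theta) {
  pos <- 1L
  for (li in seq_along(model$layers)) {
    for (nm in names(layer_param_arrays(model$layers[[li]]))) {
      cur <- model$layers[[li]][[nm]]
      len <- length(cur)
      vals <- theta[pos:(pos + len - 1L)]
      model$layers[[li]][[nm]] <-
        if (is.matrix(cur)) matrix(vals, nrow(cur), ncol(cur)) else vals
      pos <- pos + len
    }
  }
  model
}

#' Train a GNN transductively on one graph
#'
#' Minimises the cross-entropy of the training-mask nodes with full-batch
#' Adam. Message passing always runs over the whole graph, so unlabelled
#' test nodes contribute their features and connectivity but never their
#' labels. Dropout is applied to each layer's input during training only.
#' Runs are deterministic given `config$seed`.
#'
#' @param model A [build_model()] result (its current weights are the
#'   starting point only when `init_seed = NULL`; by default weights are
#'   re-initialised from the config seed so a run is a pure function of
#'   its inputs).
#' @param graph A [knn_graph()] over all nodes.
#' @param table An embedding table (or a bare feature matrix plus
#'   `labels`).
#' @param train_mask Logical or integer vector selecting supervised
#'   nodes; every class must occur in it.
#' @param config A [train_config()].
#' @param labels Optional explicit 0-based label vector (defaults to the
#'   table's).
#' @param reinit Re-initialise weights from `config$seed` before training
#'   (default `TRUE`).
#' @return A `gnn_trained` object: the fitted `model`, the per-epoch
#'   `loss_history`, and a `config` echo.
#' @export
train <- function(model, graph, table, train_mask, config = train_config(),
                  labels = NULL, reinit = TRUE) {
  stopifnot(inherits(model, "gnn_model"), inherits(graph, "knn_graph"),
            inherits(config, "train_config"))
  H0 <- if (inherits(table, "embedding_table")) feature_matrix(table) else as.matrix(table)
  y <- labels %||% (if (inherits(table, "embedding_table")) node_labels(table) else NULL)
  if (is.null(y)) abort_config("labels are required when `table` is a bare matrix")
  if (nrow(H0) != graph$n_nodes) abort_data("feature rows must match graph nodes")
  if (ncol(H0) != model$spec$d_in) abort_config("feature dimension != model d_in")

  mask_idx <- if (is.logical(train_mask)) which(train_mask) else as.integer(train_mask)
  if (length(mask_idx) == 0) abort_config("train_mask must be nonempty")
  if (anyNA(y[mask_idx])) abort_data("unlabelled node inside the train mask")
  y <- as.integer(y)
  present <- sort(unique(y[mask_idx]))
  if (!identical(present, seq_len(model$spec$n_classes) - 1L)) {
    abort_data("every class must appear in the training mask")
  }

  set.seed(config$seed)
  if (reinit) model <- build_model(model$spec, seed = NULL)
  gctx <- graph_context(graph, model$spec$arch)
  p <- model$spec$dropout
  n <- nrow(H0)

  # Adam state, one slot per parameter array
  mstate <- lapply(model$layers, function(l) {
    lapply(layer_param_arrays(l), function(x) x * 0)
  })
  vstate <- mstate
  loss_history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    masks <- NULL
    if (p > 0) {
      masks <- list(
        m1 = matrix(runif(n * ncol(H0)) >= p, n, ncol(H0)) * 1,
        m2 = matrix(runif(n * hidden_width(model$spec)) >= p, n,
                    hidden_width(model$spec)) * 1
      )
    }
    fw <- model_forward(model, gctx, H0, dropout_masks = masks)
    cl <- ce_loss(fw$logits, y, mask_idx)
    loss_history[epoch] <- cl$loss
    if (!is.finite(cl$loss)) abort_numeric("training loss diverged")

    b2 <- layer_backward(model$layers[[2]], gctx, fw$c2, cl$dlogits,
                         model$spec$arch, first = FALSE)
    dA1 <- b2$dX
    if (!is.null(masks)) dA1 <- dA1 * masks$m2 / (1 - p)
    dZ1 <- dA1 * (fw$c1$Z > 0)
    b1 <- layer_backward(model$layers[[1]], gctx, fw$c1, dZ1,
                         model$spec$arch, first = TRUE)
    grads <- list(b1$grads, b2$grads)

    t_bc1 <- 1 - config$beta1^epoch
    t_bc2 <- 1 - config$beta2^epoch
    for (li in 1:2) {
      for (nm in names(grads[[li]])) {
        g <- grads[[li]][[nm]] + config$weight_decay * model$layers[[li]][[nm]]
        mstate[[li]][[nm]] <- config$beta1 * mstate[[li]][[nm]] + (1 - config$beta1) * g
        vstate[[li]][[nm]] <- config$beta2 * vstate[[li]][[nm]] + (1 - config$beta2) * g^2
        step <- config$lr * (mstate[[li]][[nm]] / t_bc1) /
          (sqrt(vstate[[li]][[nm]] / t_bc2) + config$eps)
        model$layers[[li]][[nm]] <- model$layers[[li]][[nm]] - step
      }
    }
  }

  structure(
    list(model = model, loss_history = loss_history, config = config),
    class = "gnn_trained"
  )
}

hidden_width <- function(spec) {
  if (spec$arch == "gat") spec$heads * spec$n_hidden else spec$n_hidden
}

#' @export
print.gnn_trained <- function(x, ...) {
  cat(sprintf(
    "# gnn_trained: %s, %d epochs, final loss %.4f\n",
    toupper(x$model$spec$arch), length(x$loss_history),
    if (length(x$loss_history)) tail(x$loss_history, 1) else NA_real_
  ))
  invisible(x)
}

#' Predict class probabilities for every node
#'
#' Runs the model forward with dropout disabled and softmaxes the
#' logits; each row is a probability vector over classes summing to one.
#'
#' @param object A `gnn_model` or `gnn_trained`.
#' @param graph The [knn_graph()] the nodes live on.
#' @param table Embedding table or feature matrix for all nodes.
#' @param ... Ignored.
#' @return n x C matrix of class probabilities.
#' @export
predict.gnn_model <- function(object, graph, table, ...) {
  H0 <- if (inherits(table, "embedding_table")) feature_matrix(table) else as.matrix(table)
  if (ncol(H0) != object$spec$d_in) abort_config("feature dimension != model d_in")
  gctx <- graph_context(graph, object$spec$arch)
  fw <- model_forward(object, gctx, H0, dropout_masks = NULL)
  softmax_rows(fw$logits)
}

#' @rdname predict.gnn_model
#' @export
predict.gnn_trained <- function(object, graph, table, ...) {
  predict(object$model, graph, table, ...)
}

#' Hard labels from a probability matrix
#'
#' @param probs n x C probability (or logit) matrix.
#' @return Integer vector of 0-based predicted labels.
#' @export
predicted_labels <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}

#' @method tidy gnn_trained
#' @export
tidy.gnn_trained <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @method glance gnn_trained
#' @export
glance.gnn_trained <- function(x, ...) {
  tibble::tibble(
    arch = x$model$spec$arch,
    epochs = length(x$loss_history),
    final_loss = if (length(x$loss_history)) tail(x$loss_history, 1) else NA_real_,
    n_parameters = count_parameters(x$model)
  )
}

#' Training-loss curve
#'
#' @param object A `gnn_trained`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gnn_trained
#' @export
autoplot.gnn_trained <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training cross-entropy") +
    ggplot2::theme_minimal()
}
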