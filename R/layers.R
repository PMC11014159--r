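#' Layer parameter bundles
#'
#' Constructors for the trainable tensors of the three message-passing
#' layers.
#'
#' * GCN: one weight matrix `W` (d_in x d_out) and a bias.
#' * GraphSAGE: a neighbour-aggregate transform `W` (carrying the layer
#'   bias) and a separate self transform `B` without bias; the layer
#'   computes `act(mean_{v in N_u}(h_v) W + h_u B + bias)`, the summed
#'   form that is parameter-identical to concatenating neighbourhood and
#'   self features before one wide transform.
#' * GAT: two biased input transforms — `W_l` applied to the target
#'   (attending) node and `W_r` applied to the source (attended) node —
#'   each d_in x (heads * d_head), an attention vector `a` of length
#'   heads * d_head, and an additive output bias.
#'
#' @param W,B,W_l,W_r Weight matrices (see above).
#' @param bias,b_l,b_r,out_bias Bias vectors.
#' @param a Attention vector, length `heads * d_head`.
#' @param heads Number of attention heads.
#' @param leaky_slope Negative slope of the LeakyReLU inside the
#'   attention score (0.2).
#' @return A parameter list of class `gcn_params` / `sage_params` /
#'   `gat_params`.
#' @name layer-params
NULL

#' @rdname layer-params
#' @export
gcn_layer_params <- function(W, bias = numeric(ncol(W))) {
  W <- as.matrix(W)
  if (length(bias) != ncol(W)) abort_config("bias length must equal d_out")
  structure(list(W = W, bias = as.numeric(bias)), class = "gcn_params")
}

#' @rdname layer-params
#' @export
sage_layer_params <- function(W, B, bias = numeric(ncol(W))) {
  W <- as.matrix(W); B <- as.matrix(B)
  if (!identical(dim(W), dim(B))) abort_config("W and B must have equal shape")
  if (length(bias) != ncol(W)) abort_config("bias length must equal d_out")
  structure(list(W = W, B = B, bias = as.numeric(bias)), class = "sage_params")
}

#' @rdname layer-params
#' @export
gat_layer_params <- function(W_l, W_r, a,
                             b_l = numeric(ncol(W_l)),
                             b_r = numeric(ncol(W_r)),
                             out_bias = NULL,
                             heads = 1L, leaky_slope = 0.2) {
  W_l <- as.matrix(W_l); W_r <- as.matrix(W_r)
  Fdim <- ncol(W_l)
  if (!identical(dim(W_l), dim(W_r))) abort_config("W_l, W_r must match in shape")
  if (Fdim %% heads != 0) abort_config("width must be divisible by heads")
  if (length(a) != Fdim) abort_config("attention vector must have length heads * d_head")
  d_head <- Fdim %/% heads
  if (is.null(out_bias)) out_bias <- numeric(Fdim)
  structure(
    list(
      W_l = W_l, b_l = as.numeric(b_l), W_r = W_r, b_r = as.numeric(b_r),
      a = as.numeric(a), out_bias = as.numeric(out_bias),
      heads = as.integer(heads), d_head = as.integer(d_head),
      leaky_slope = leaky_slope
    ),
    class = "gat_params"
  )
}

relu <- function(x) x * (x > 0)
leaky_relu <- function(x, slope) x * (x > 0) + slope * x * (x <= 0)

add_bias <- function(M, bias) M + rep(bias, each = nrow(M))

check_layer_input <- function(H, params_din, what) {
  if (ncol(H) != params_din) {
    abort_config(sprintf("%s: input has %d columns, parameters expect %d",
                         what, ncol(H), params_din))
  }
}

#' Graph-convolution layer (symmetric-normalised propagation)
#'
#' Computes `activation(S H W + bias)` with the propagation operator
#' `S = D^{-1/2} (A + I) D^{-1/2}` built from the graph's self-looped
#' adjacency — each node averages its own and its neighbours' transformed
#' features with inverse-square-root degree weights. Evaluated by sparse
#' aggregation; agrees with the dense matrix formula to machine
#' precision.
#'
#' @param H Node feature matrix, n x d_in.
#' @param graph A [knn_graph()].
#' @param params [gcn_layer_params()].
#' @param activation Elementwise activation (default identity).
#' @return n x d_out matrix.
#' @export
gcn_layer <- function(H, graph, params, activation = identity) {
  stopifnot(inherits(params, "gcn_params"))
  H <- as.matrix(H)
  check_layer_input(H, nrow(params$W), "gcn_layer")
  S <- gcn_propagator(graph)
  Z <- add_bias(as.matrix(S %*% (H %*% params$W)), params$bias)
  activation(Z)
}

#' GraphSAGE layer (mean aggregator)
#'
#' Computes `activation(mean_{v in N_u}(h_v) W + h_u B + bias)`: the mean
#' of the in-neighbourhood is transformed by `W`, the node's own features
#' by `B`, and the two are summed. No self-loop is added — self
#' information flows only through `B` — and a node with an empty
#' neighbourhood aggregates the zero vector.
#'
#' @inheritParams gcn_layer
#' @param params [sage_layer_params()].
#' @return n x d_out matrix.
#' @export
sage_layer <- function(H, graph, params, activation = identity) {
  stopifnot(inherits(params, "sage_params"))
  H <- as.matrix(H)
  check_layer_input(H, nrow(params$W), "sage_layer")
  M <- mean_aggregator(graph)
  Z <- add_bias(
    as.matrix(M %*% H) %*% params$W + H %*% params$B,
    params$bias
  )
  activation(Z)
}

# Attention edge context: edges plus one self-loop per node, sorted by
# target; `groups[[u]]` indexes the rows attending to node u.
gat_edge_context <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  src <- c(e[, 1], seq_len(n))
  dst <- c(e[, 2], seq_len(n))
  o <- order(dst, src)
  src <- src[o]
  dst <- dst[o]
  # every node carries its self-loop, so rowsum() over either endpoint
  # always yields one row per node, in node order
  list(n = n, src = src, dst = dst, groups = split(seq_along(src), dst))
}

# Full attention-layer forward with caches for the backward pass.
# Vectorised across heads: `hd` maps each of the F = heads * d_head
# columns to its head, and per-head dot products with the attention
# vector become one m x F by F x heads multiply.
gat_forward <- function(H, ctx, params, concat) {
  heads <- params$heads
  d_head <- params$d_head
  Fdim <- heads * d_head
  slope <- params$leaky_slope
  hd <- rep(seq_len(heads), each = d_head)
  m <- length(ctx$src)

  G <- add_bias(H %*% params$W_l, params$b_l) # target-side transform
  S <- add_bias(H %*% params$W_r, params$b_r) # source-side transform
  Se <- S[ctx$src, , drop = FALSE]
  Tm <- G[ctx$dst, , drop = FALSE] + Se
  pos <- Tm > 0
  R <- Tm * (slope + (1 - slope) * pos)

  aw <- matrix(0, Fdim, heads)
  aw[cbind(seq_len(Fdim), hd)] <- params$a
  L <- R %*% aw # m x heads attention logits

  # Per-target, per-head softmax. A shift common to a whole neighbourhood
  # cancels in the ratio, so subtracting the per-head global maximum is
  # exact and cheap; only if an entire neighbourhood underflows do we
  # redo it with the per-neighbourhood maximum.
  E <- exp(L - rep(apply(L, 2, max), each = m))
  denom <- rowsum(E, ctx$dst, reorder = TRUE)
  if (any(denom == 0)) {
    gm <- vapply(
      ctx$groups,
      function(ix) apply(L[ix, , drop = FALSE], 2, max),
      numeric(heads)
    )
    gmax <- t(matrix(gm, nrow = heads)) # n x heads, robust to heads == 1
    E <- exp(L - gmax[ctx$dst, , drop = FALSE])
    denom <- rowsum(E, ctx$dst, reorder = TRUE)
  }
  alpha <- E / denom[ctx$dst, , drop = FALSE]
  alpha_full <- alpha[, hd, drop = FALSE] # m x F, head-replicated

  O <- rowsum(Se * alpha_full, ctx$dst, reorder = TRUE)
  dimnames(O) <- NULL
  if (concat) {
    Z <- add_bias(O, params$out_bias)
  } else {
    avg <- matrix(0, ctx$n, d_head)
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * d_head + 1L):(h * d_head)
      avg <- avg + O[, idx, drop = FALSE]
    }
    Z <- add_bias(avg / heads, params$out_bias)
  }
  list(H = H, G = G, S = S, Se = Se, pos = pos, R = R,
       alpha = alpha, alpha_full = alpha_full, O = O, Z = Z)
}

#' Attention coefficients of a GAT layer
#'
#' For every node u and every head, scores each attended node v in
#' `N_u ∪ {u}` (the in-neighbourhood plus a self-loop) as
#' `e_uv = a' LeakyReLU(W_l h_u + W_r h_v)` and normalises with a softmax
#' over v, so the coefficients for each (u, head) sum to one.
#'
#' @inheritParams gcn_layer
#' @param params [gat_layer_params()].
#' @return Tibble with columns `target`, `source`, `head`, `alpha`.
#' @export
attention_coefficients <- function(H, graph, params) {
  stopifnot(inherits(params, "gat_params"))
  H <- as.matrix(H)
  check_layer_input(H, nrow(params$W_l), "attention_coefficients")
  ctx <- gat_edge_context(graph)
  fw <- gat_forward(H, ctx, params, concat = TRUE)
  tibble::tibble(
    target = rep(ctx$dst, params$heads),
    source = rep(ctx$src, params$heads),
    head = rep(seq_len(params$heads), each = length(ctx$src)),
    alpha = as.vector(fw$alpha)
  )
}

#' Graph-attention layer
#'
#' Per head, each node aggregates the source-transformed features
#' `W_r h_v` of its attended nodes (in-neighbours plus itself), weighted
#' by the softmax attention coefficients of
#' [attention_coefficients()]; head outputs are concatenated
#' (`concat = TRUE`, hidden layers) or averaged (`concat = FALSE`, final
#' layer), an output bias is added, and the activation applied.
#'
#' @inheritParams gcn_layer
#' @param params [gat_layer_params()].
#' @param concat Concatenate head outputs (`TRUE`) or average them.
#' @return n x (heads * d_head) matrix if `concat`, else n x d_head.
#' @export
gat_layer <- function(H, graph, params, activation = identity, concat = TRUE) {
  stopifnot(inherits(params, "gat_params"))
  H <- as.matrix(H)
  check_layer_input(H, nrow(params$W_l), "gat_layer")
  ctx <- gat_edge_context(graph)
  activation(gat_forward(H, ctx, params, concat)$Z)
}
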