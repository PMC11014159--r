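# Independent reference implementations used as oracles. Everything here
# is deliberately naive (explicit loops, dense algebra) and shares no
# code with the package internals it checks.

# Brute-force k-NN: full pairwise distance table, per-node selection with
# the lower-index tie-break.
oracle_knn_edges <- function(X, k, metric = "euclidean") {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (metric == "euclidean") {
        D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
      } else {
        D[i, j] <- 1 - sum(X[i, ] * X[j, ]) /
          (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
      }
    }
  }
  edges <- matrix(0L, n * k, 2)
  row <- 0L
  for (u in seq_len(n)) {
    cand <- setdiff(seq_len(n), u)
    cand <- cand[order(D[cand, u], cand)]
    for (v in cand[seq_len(k)]) {
      row <- row + 1L
      edges[row, ] <- c(v, u)
    }
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Dense adjacency built straight from the edge set.
oracle_adjacency <- function(graph) {
  A <- matrix(0, graph$n_nodes, graph$n_nodes)
  e <- graph$edges
  for (r in seq_len(nrow(e))) A[e[r, 2], e[r, 1]] <- 1
  A
}

# Dense evaluation of the symmetric-normalised propagation rule.
oracle_gcn <- function(H, graph, params, activation = identity) {
  A_tilde <- oracle_adjacency(graph) + diag(graph$n_nodes)
  d <- rowSums(A_tilde)
  S <- diag(1 / sqrt(d)) %*% A_tilde %*% diag(1 / sqrt(d))
  activation(S %*% H %*% params$W +
               matrix(params$bias, nrow(H), length(params$bias), byrow = TRUE))
}

# Per-node mean-aggregate-then-transform loop.
oracle_sage <- function(H, graph, params, activation = identity) {
  n <- graph$n_nodes
  out <- matrix(0, n, ncol(params$W))
  for (u in seq_len(n)) {
    nbrs <- graph$edges[graph$edges[, 2] == u, 1]
    agg <- if (length(nbrs) == 0) {
      rep(0, ncol(H))
    } else {
      colMeans(H[nbrs, , drop = FALSE])
    }
    out[u, ] <- agg %*% params$W + H[u, ] %*% params$B + params$bias
  }
  activation(out)
}

# Literal per-node, per-head attention: score every attended node with
# a' LeakyReLU(W_l h_u + W_r h_v), softmax, aggregate W_r h_v.
oracle_gat <- function(H, graph, params, activation = identity,
                       concat = TRUE) {
  n <- graph$n_nodes
  heads <- params$heads
  d_head <- params$d_head
  lrelu <- function(x) ifelse(x > 0, x, params$leaky_slope * x)
  G <- H %*% params$W_l + matrix(params$b_l, n, length(params$b_l), byrow = TRUE)
  S <- H %*% params$W_r + matrix(params$b_r, n, length(params$b_r), byrow = TRUE)
  O <- matrix(0, n, heads * d_head)
  alpha_log <- list()
  for (u in seq_len(n)) {
    nbrs <- sort(unique(c(graph$edges[graph$edges[, 2] == u, 1], u)))
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * d_head + 1):(h * d_head)
      scores <- vapply(nbrs, function(v) {
        sum(params$a[idx] * lrelu(G[u, idx] + S[v, idx]))
      }, numeric(1))
      w <- exp(scores - max(scores))
      alpha <- w / sum(w)
      alpha_log[[length(alpha_log) + 1L]] <-
        data.frame(target = u, source = nbrs, head = h, alpha = alpha)
      for (i in seq_along(nbrs)) {
        O[u, idx] <- O[u, idx] + alpha[i] * S[nbrs[i], idx]
      }
    }
  }
  if (!concat) {
    avg <- matrix(0, n, d_head)
    for (h in seq_len(heads)) {
      avg <- avg + O[, ((h - 1) * d_head + 1):(h * d_head), drop = FALSE]
    }
    O <- avg / heads
  }
  Z <- O + matrix(params$out_bias, n, length(params$out_bias), byrow = TRUE)
  list(out = activation(Z), alpha = do.call(rbind, alpha_log))
}

# Random homophilous test instance: features, a k-NN graph and random
# layer parameters for each architecture.
random_instance <- function(seed, n = NULL, arch = "gcn", heads = 1L,
                            symmetrized = TRUE) {
  set.seed(seed)
  n <- if (is.null(n)) sample(5:50, 1) else n
  d_in <- sample(2:6, 1)
  d_out <- sample(2:5, 1)
  k <- sample(seq_len(min(n - 1, 4)), 1)
  X <- matrix(rnorm(n * d_in), n, d_in)
  graph <- knn_graph(X, k = k, symmetrized = symmetrized)
  params <- switch(arch,
    gcn = gcn_layer_params(matrix(rnorm(d_in * d_out), d_in, d_out),
                           rnorm(d_out)),
    sage = sage_layer_params(matrix(rnorm(d_in * d_out), d_in, d_out),
                             matrix(rnorm(d_in * d_out), d_in, d_out),
                             rnorm(d_out)),
    gat = gat_layer_params(
      W_l = matrix(rnorm(d_in * heads * d_out), d_in, heads * d_out),
      W_r = matrix(rnorm(d_in * heads * d_out), d_in, heads * d_out),
      a = rnorm(heads * d_out),
      b_l = rnorm(heads * d_out), b_r = rnorm(heads * d_out),
      out_bias = rnorm(heads * d_out), heads = heads
    )
  )
  list(X = X, graph = graph, params = params, n = n, d_in = d_in,
       d_out = d_out, k = k)
}

# Build a graph from an explicit 1-based edge matrix (testing back door).
graph_from_edges <- function(n, edges) {
  audiograph:::new_knn_graph(n, edges, k = NA_integer_,
                             metric = "euclidean", symmetrized = FALSE)
}

# Central finite-difference gradient of the training loss.
numeric_gradient <- function(model, gctx, H0, y, mask, eps = 1e-6) {
  theta <- audiograph:::flatten_params(model)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    lp <- audiograph:::model_loss(
      audiograph:::unflatten_params(model, tp), gctx, H0, y, mask)
    lm <- audiograph:::model_loss(
      audiograph:::unflatten_params(model, tm), gctx, H0, y, mask)
    (lp - lm) / (2 * eps)
  }, numeric(1))
}

flat_gradients <- function(grads) {
  unlist(lapply(grads, function(l) lapply(l, as.numeric)), use.names = FALSE)
}

# Hop distances from node u along the undirected version of the edges.
hop_distances <- function(graph, u) {
  n <- graph$n_nodes
  e <- rbind(graph$edges, graph$edges[, 2:1])
  dist <- rep(Inf, n)
  dist[u] <- 0
  frontier <- u
  h <- 0
  while (length(frontier) > 0) {
    h <- h + 1
    nxt <- unique(e[e[, 1] %in% frontier, 2])
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- h
    frontier <- nxt
  }
  dist
}
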