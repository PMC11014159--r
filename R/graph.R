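#' k-nearest-neighbour graphs over embedding space
#'
#' `knn_edges()` computes, for every node u, its k nearest distinct nodes
#' v under the chosen metric and adds directed edges v -> u, so that u's
#' in-neighbourhood N_u is exactly its k nearest neighbours. Distances are
#' exact (full pairwise computation); ties are broken towards the lower
#' node index so results are deterministic. `symmetrize()` replaces the
#' edge set with its union with all reversed pairs, the form assumed by
#' symmetric-normalised propagation. `knn_graph()` is the common
#' composition of the two.
#'
#' Self-loops never appear in the stored edge set; propagation operators
#' that need them (the self-looped adjacency, attention neighbourhoods)
#' add them as derived views.
#'
#' @param features Numeric matrix (n x d) or an embedding table.
#' @param k Number of neighbours, `1 <= k <= n - 1`.
#' @param metric `"euclidean"` or `"cosine"` (cosine distance
#'   `1 - cos(angle)`; zero-norm rows are an error).
#' @return A `knn_graph`: list with `n_nodes`, `edges` (m x 2 integer
#'   matrix of 1-based `(source, target)` pairs, sorted), `k`, `metric`,
#'   `symmetrized`.
#' @examples
#' x <- rbind(c(0, 0), c(1, 0), c(3, 0))
#' knn_edges(x, k = 1)$edges
#' @export
knn_edges <- function(features, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (inherits(features, "embedding_table")) features <- feature_matrix(features)
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1 || k >= n) abort_config("need 1 <= k <= n_nodes - 1")
  k <- as.integer(k)

  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(features))
  } else {
    nrm <- sqrt(rowSums(features^2))
    if (any(nrm == 0)) {
      abort_data("cosine metric undefined for zero-norm feature vectors")
    }
    U <- features / nrm
    D <- 1 - tcrossprod(U)
  }
  diag(D) <- Inf

  src <- integer(n * k)
  for (u in seq_len(n)) {
    # stable two-key order: distance, then node index (the tie-break)
    nb <- order(D[, u], seq_len(n))[seq_len(k)]
    src[((u - 1L) * k + 1L):(u * k)] <- nb
  }
  edges <- cbind(source = src, target = rep(seq_len(n), each = k))
  new_knn_graph(n, edges, k, metric, symmetrized = FALSE)
}

new_knn_graph <- function(n_nodes, edges, k, metric, symmetrized) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      abort_data("edge endpoints out of range")
    }
    if (any(edges[, 1] == edges[, 2])) {
      abort_data("self-loops are not stored in the edge set")
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges, k = k,
         metric = metric, symmetrized = isTRUE(symmetrized)),
    class = "knn_graph"
  )
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf(
    "# knn_graph: %d nodes, %d edges (k = %s, %s, %s)\n",
    x$n_nodes, nrow(x$edges), x$k %||% "?", x$metric,
    if (x$symmetrized) "symmetrized" else "directed"
  ))
  invisible(x)
}

#' @rdname knn_edges
#' @param graph A `knn_graph`.
#' @export
symmetrize <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  e <- graph$edges
  both <- unique(rbind(e, e[, 2:1, drop = FALSE]))
  new_knn_graph(graph$n_nodes, both, graph$k, graph$metric, symmetrized = TRUE)
}

#' @rdname knn_edges
#' @param symmetrized Whether to symmetrize the k-NN digraph (the
#'   default; symmetric normalisation presumes an undirected adjacency).
#' @export
knn_graph <- function(features, k, metric = c("euclidean", "cosine"),
                      symmetrized = TRUE) {
  g <- knn_edges(features, k, metric)
  if (symmetrized) symmetrize(g) else g
}

#' Adjacency, self-looped adjacency and degree matrices
#'
#' Returns the binary adjacency `A` (`A[u, v] = 1` iff `v` is an
#' in-neighbour of `u`), the self-looped adjacency `A_tilde = A + I`, and
#' the diagonal degree matrix `D_tilde` of the self-looped adjacency, as
#' sparse matrices.
#'
#' @param graph A `knn_graph`.
#' @return List with sparse matrices `A`, `A_tilde`, `D_tilde`.
#' @export
graph_matrices <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  n <- graph$n_nodes
  e <- graph$edges
  A <- Matrix::sparseMatrix(
    i = e[, 2], j = e[, 1], x = 1, dims = c(n, n)
  )
  A_tilde <- A + Matrix::Diagonal(n)
  D_tilde <- Matrix::Diagonal(n, x = Matrix::rowSums(A_tilde))
  list(A = A, A_tilde = A_tilde, D_tilde = D_tilde)
}

# D^{-1/2} (A + I) D^{-1/2}, the GCN propagation operator.
gcn_propagator <- function(graph) {
  m <- graph_matrices(graph)
  d_inv_sqrt <- Matrix::Diagonal(graph$n_nodes, 1 / sqrt(Matrix::diag(m$D_tilde)))
  d_inv_sqrt %*% m$A_tilde %*% d_inv_sqrt
}

# Row-stochastic-where-defined mean aggregation over in-neighbours;
# all-zero rows for nodes with no in-neighbours (SAGE convention).
mean_aggregator <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  deg_in <- tabulate(e[, 2], nbins = n)
  w <- 1 / deg_in[e[, 2]]
  Matrix::sparseMatrix(i = e[, 2], j = e[, 1], x = w, dims = c(n, n))
}

# In-neighbour lists: nbrs[[u]] = sources v with an edge v -> u.
in_neighbours <- function(graph) {
  out <- vector("list", graph$n_nodes)
  e <- graph$edges
  if (nrow(e) > 0) {
    sp <- split(e[, 1], factor(e[, 2], levels = seq_len(graph$n_nodes)))
    out <- lapply(sp, as.integer)
  } else {
    out <- rep(list(integer()), graph$n_nodes)
  }
  out
}

#' Edge homophily of a labelled graph
#'
#' Fraction of edges whose endpoints share a label — the quantity that
#' governs how informative message passing is for node classification.
#'
#' @param graph A `knn_graph`.
#' @param labels Integer label per node.
#' @return A real in \[0, 1\].
#' @export
graph_homophily <- function(graph, labels) {
  e <- graph$edges
  if (nrow(e) == 0) return(NA_real_)
  mean(labels[e[, 1]] == labels[e[, 2]])
}

#' Read and write edge lists
#'
#' Tab-separated `source<TAB>target` pairs, one edge per line, 0-based
#' node indices, sorted by `(source, target)`. `read_edge_list()` needs
#' `n_nodes` because isolated nodes leave no trace in the file.
#'
#' @param graph A `knn_graph`.
#' @param path File path.
#' @return `write_edge_list()` returns `path` invisibly;
#'   `read_edge_list()` a `knn_graph`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "knn_graph"))
  e <- graph$edges - 1L # 0-based on disk
  writeLines(if (nrow(e)) paste(e[, 1], e[, 2], sep = "\t") else character(), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes Number of nodes in the graph the file describes.
#' @param ... Metadata (`k`, `metric`, `symmetrized`) to attach.
#' @export
read_edge_list <- function(path, n_nodes, ...) {
  if (!file.exists(path)) abort_data(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  meta <- list(...)
  if (length(lines) == 0) {
    edges <- matrix(integer(), ncol = 2)
  } else {
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    edges <- matrix(as.integer(parts), ncol = 2) + 1L
  }
  new_knn_graph(
    n_nodes, edges,
    k = meta$k %||% NA_integer_,
    metric = meta$metric %||% "euclidean",
    symmetrized = meta$symmetrized %||% FALSE
  )
}
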