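test_that("gcn layer handles the degenerate single-node case and zero weights", {
  g <- graph_from_edges(1, matrix(integer(), 0, 2))
  h <- matrix(c(1.5, -2), 1, 2)
  params <- gcn_layer_params(matrix(c(1, 0, 2, 1), 2, 2), c(0.5, -0.5))
  # A_tilde = D_tilde = I, so the layer is just the affine transform
  expect_equal(gcn_layer(h, g, params), h %*% params$W +
                 matrix(params$bias, 1, 2, byrow = TRUE))

  set.seed(2)
  g2 <- knn_graph(matrix(rnorm(20), 10, 2), k = 2)
  zero <- gcn_layer_params(matrix(0, 2, 3), numeric(3))
  expect_equal(gcn_layer(matrix(rnorm(20), 10, 2), g2, zero),
               matrix(0, 10, 3))
})

test_that("each layer matches its dense or naive oracle on random instances", {
  for (seed in 1:10) {
    inst <- random_instance(seed, arch = "gcn")
    expect_equal(gcn_layer(inst$X, inst$graph, inst$params, relu),
                 oracle_gcn(inst$X, inst$graph, inst$params, relu),
                 tolerance = 1e-6)

    inst <- random_instance(seed + 100, arch = "sage")
    expect_equal(sage_layer(inst$X, inst$graph, inst$params, relu),
                 oracle_sage(inst$X, inst$graph, inst$params, relu),
                 tolerance = 1e-6)

    inst <- random_instance(seed + 200, arch = "gat",
                            heads = sample(1:3, 1))
    ref <- oracle_gat(inst$X, inst$graph, inst$params)
    expect_equal(gat_layer(inst$X, inst$graph, inst$params),
                 ref$out, tolerance = 1e-6)
  }
})

test_that("sage treats empty neighbourhoods as zero aggregate", {
  # node 3 has no in-edges
  g <- graph_from_edges(3, rbind(c(2L, 1L), c(1L, 2L)))
  H <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  params <- sage_layer_params(W = diag(2), B = matrix(0.5, 2, 2) * diag(2),
                              bias = c(1, 1))
  out <- sage_layer(H, g, params)
  expect_equal(out[3, ], H[3, ] %*% params$B + c(1, 1), ignore_attr = TRUE)
  # node 1's single neighbour with W = I, B = 0, bias = 0 is passed through
  params2 <- sage_layer_params(W = diag(2), B = matrix(0, 2, 2))
  expect_equal(sage_layer(H, g, params2)[1, ], H[2, ])
})

test_that("attention coefficients form a softmax over each neighbourhood", {
  # isolated node: only the self-loop attends, so alpha = 1
  g <- graph_from_edges(2, rbind(c(1L, 2L)))
  set.seed(3)
  params <- gat_layer_params(
    W_l = matrix(rnorm(6), 2, 3), W_r = matrix(rnorm(6), 2, 3),
    a = rnorm(3), heads = 1L
  )
  H <- matrix(rnorm(4), 2, 2)
  co <- attention_coefficients(H, g, params)
  expect_equal(co$alpha[co$target == 1], 1)

  # identical features make every attended node equally weighted
  g3 <- graph_from_edges(3, rbind(c(2L, 1L), c(3L, 1L)))
  Hc <- matrix(1, 3, 2)
  co3 <- attention_coefficients(Hc, g3, params)
  expect_equal(co3$alpha[co3$target == 1], rep(1 / 3, 3))

  # normalisation holds on random instances, and every coefficient
  # matches the literal per-edge softmax
  for (seed in 1:5) {
    inst <- random_instance(seed + 300, arch = "gat", heads = 2L)
    co <- attention_coefficients(inst$X, inst$graph, inst$params)
    sums <- tapply(co$alpha, interaction(co$target, co$head), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    ref <- oracle_gat(inst$X, inst$graph, inst$params)$alpha
    merged <- merge(as.data.frame(co), ref,
                    by = c("target", "source", "head"))
    expect_equal(merged$alpha.x, merged$alpha.y, tolerance = 1e-9)
  }
})

test_that("gat reduces to mean aggregation when attention is uniform", {
  set.seed(9)
  g <- symmetrize(knn_edges(matrix(rnorm(10), 5, 2), k = 2))
  H <- matrix(1, 5, 2) # identical features force uniform attention
  params <- gat_layer_params(
    W_l = matrix(rnorm(4), 2, 2), W_r = matrix(rnorm(4), 2, 2),
    a = rnorm(2), b_l = rnorm(2), b_r = rnorm(2), out_bias = rnorm(2),
    heads = 1L
  )
  out <- gat_layer(H, g, params)
  expect_true(all(abs(sweep(out, 2, out[1, ])) < 1e-12)) # identical rows
  # and equals the mean of source-transformed features over N_u + self
  s <- H[1, ] %*% params$W_r + params$b_r
  expect_equal(out[1, ], as.numeric(s + params$out_bias))
})

test_that("layers are permutation-equivariant", {
  set.seed(11)
  n <- 20
  d_in <- 3
  d_out <- 4
  X <- matrix(rnorm(n * d_in), n, d_in)
  perm <- sample(n)
  g <- knn_graph(X, k = 3)
  gp <- knn_graph(X[perm, , drop = FALSE], k = 3)
  params <- list(
    gcn = gcn_layer_params(matrix(rnorm(d_in * d_out), d_in, d_out),
                           rnorm(d_out)),
    sage = sage_layer_params(matrix(rnorm(d_in * d_out), d_in, d_out),
                             matrix(rnorm(d_in * d_out), d_in, d_out),
                             rnorm(d_out)),
    gat = gat_layer_params(
      W_l = matrix(rnorm(d_in * 2 * d_out), d_in, 2 * d_out),
      W_r = matrix(rnorm(d_in * 2 * d_out), d_in, 2 * d_out),
      a = rnorm(2 * d_out), b_l = rnorm(2 * d_out), b_r = rnorm(2 * d_out),
      out_bias = rnorm(2 * d_out), heads = 2L
    )
  )
  apply_layer <- function(arch, H, graph) {
    switch(arch,
      gcn = gcn_layer(H, graph, params$gcn, relu),
      sage = sage_layer(H, graph, params$sage, relu),
      gat = gat_layer(H, graph, params$gat)
    )
  }
  for (arch in c("gcn", "sage", "gat")) {
    out <- apply_layer(arch, X, g)
    outp <- apply_layer(arch, X[perm, , drop = FALSE], gp)
    expect_equal(outp, out[perm, ], tolerance = 1e-10)
  }
})

test_that("two-layer models are local to the 2-hop neighbourhood", {
  # path graph 1-2-3-4-5-6
  edges <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L),
                 c(3L, 4L), c(4L, 3L), c(4L, 5L), c(5L, 4L),
                 c(5L, 6L), c(6L, 5L))
  g <- graph_from_edges(6, edges)
  set.seed(13)
  H <- matrix(rnorm(12), 6, 2)
  dists <- hop_distances(g, 1)
  expect_equal(dists, c(0, 1, 2, 3, 4, 5))
  for (arch in c("gcn", "sage", "gat")) {
    model <- build_model(model_spec(arch, d_in = 2, n_hidden = 3,
                                    n_classes = 2, heads = 2, dropout = 0),
                         seed = 21)
    base <- predict(model, g, H)
    H_far <- H
    H_far[4, ] <- H_far[4, ] + 50 # 3 hops from node 1
    moved <- predict(model, g, H_far)
    expect_equal(moved[1, ], base[1, ], tolerance = 1e-9)
    H_near <- H
    H_near[3, ] <- H_near[3, ] + 50 # 2 hops: must propagate
    expect_false(isTRUE(all.equal(predict(model, g, H_near)[1, ], base[1, ])))
  }
})
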