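nearest_centroid_accuracy <- function(tbl) {
  X <- feature_matrix(tbl)
  y <- node_labels(tbl)
  tr <- tbl$split == "train"
  centroids <- sapply(sort(unique(y[tr])), function(c) {
    colMeans(X[tr & y == c, , drop = FALSE])
  })
  pred <- apply(X[!tr, , drop = FALSE], 1, function(x) {
    which.min(colSums((centroids - x)^2)) - 1L
  })
  mean(pred == y[!tr])
}

test_that("identical seeds reproduce the table bit for bit", {
  spec <- synthetic_spec(80, d = 6, n_classes = 3, class_sep = 2, seed = 42)
  expect_identical(generate_embeddings(spec), generate_embeddings(spec))
  spec2 <- synthetic_spec(80, d = 6, n_classes = 3, class_sep = 2, seed = 43)
  expect_false(identical(generate_embeddings(spec),
                         generate_embeddings(spec2)))
})

test_that("class counts follow the proportions by largest remainder", {
  tbl <- generate_embeddings(synthetic_spec(
    1000, d = 4, n_classes = 3, class_sep = 1,
    class_proportions = c(0.2, 0.2, 0.6), seed = 1
  ))
  counts <- as.integer(table(node_labels(tbl)))
  expect_equal(counts, c(200, 200, 600))
})

test_that("fold assignment is stratified within one node per class", {
  tbl <- generate_embeddings(synthetic_spec(
    230, d = 5, n_classes = 3, class_sep = 2,
    class_proportions = c(0.5, 0.3, 0.2), n_folds = 10, seed = 3
  ))
  tab <- table(tbl$fold, node_labels(tbl))
  global <- as.integer(table(node_labels(tbl)))
  for (f in seq_len(10)) {
    expected <- global * sum(tab[f, ]) / nrow(tbl)
    expect_true(all(abs(tab[f, ] - expected) <= 1))
  }
})

test_that("zero separation carries no label signal", {
  accs <- vapply(1:5, function(s) {
    nearest_centroid_accuracy(generate_embeddings(synthetic_spec(
      100, d = 8, n_classes = 2, class_sep = 0, seed = s
    )))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("widely separated classes are 1-NN perfect on held-out nodes", {
  tbl <- generate_embeddings(synthetic_spec(
    300, d = 16, n_classes = 3, class_sep = 10, seed = 7
  ))
  X <- feature_matrix(tbl)
  y <- node_labels(tbl)
  tr <- which(tbl$split == "train")
  te <- which(tbl$split == "test")
  # brute-force 1-NN over the generated points
  pred <- vapply(te, function(i) {
    d2 <- colSums((t(X[tr, , drop = FALSE]) - X[i, ])^2)
    y[tr[which.min(d2)]]
  }, integer(1))
  expect_gte(mean(pred == y[te]), 0.99)
})

test_that("downstream accuracy is non-decreasing in class separation", {
  mean_acc <- function(sep) {
    mean(vapply(1:5, function(s) {
      nearest_centroid_accuracy(generate_embeddings(synthetic_spec(
        150, d = 8, n_classes = 3, class_sep = sep, seed = 10 + s
      )))
    }, numeric(1)))
  }
  accs <- vapply(c(0, 2, 5, 10), mean_acc, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("the land-cover imbalance preset scales to any node count", {
  p <- landcover_proportions()
  expect_equal(sum(p), 1)
  expect_equal(unname(round(p, 2)), c(0.20, 0.21, 0.59))
  tbl <- generate_embeddings(synthetic_spec(
    1000, d = 4, n_classes = 3, class_sep = 1, class_proportions = unname(p),
    seed = 2
  ))
  counts <- as.integer(table(node_labels(tbl)))
  expect_true(all(abs(counts - 1000 * p) <= 1))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(10, 4, 3, class_sep = -1), "nonnegative")
  expect_error(synthetic_spec(2, 4, 3), "n_nodes")
  expect_error(synthetic_spec(10, 2, 3, class_sep = 1), "equidistant")
  expect_error(synthetic_spec(10, 4, 2, class_proportions = c(0.7, 0.2)),
               "summing to 1")
})
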