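make_training_fixture <- function(n = 60, d = 6, C = 3, sep = 6, seed = 17,
                                  k = 4) {
  tbl <- generate_embeddings(synthetic_spec(n, d = d, n_classes = C,
                                            class_sep = sep, seed = seed))
  list(tbl = tbl, graph = knn_graph(tbl, k = k),
       train = tbl$split == "train", test = tbl$split == "test")
}

test_that("hand-derived gradients pass finite-difference checks", {
  fx <- make_training_fixture(n = 18, d = 4, C = 3, k = 3)
  H0 <- feature_matrix(fx$tbl)
  y <- node_labels(fx$tbl)
  mask <- which(fx$train)
  for (arch in c("gcn", "sage", "gat")) {
    model <- build_model(model_spec(arch, 4, 3, 3, heads = 2, dropout = 0),
                         seed = 31)
    gctx <- audiograph:::graph_context(fx$graph, arch)
    analytic <- flat_gradients(
      audiograph:::model_gradients(model, gctx, H0, y, mask)$grads
    )
    numeric <- numeric_gradient(model, gctx, H0, y, mask)
    expect_lt(max(abs(analytic - numeric)) / max(abs(numeric)), 1e-4)
  }
})

test_that("zero epochs returns the initialisation unchanged", {
  fx <- make_training_fixture()
  spec <- model_spec("gcn", 6, 8, 3)
  fit <- train(build_model(spec), fx$graph, fx$tbl, fx$train,
               train_config(epochs = 0, seed = 7))
  expect_equal(fit$model$layers, build_model(spec, seed = 7)$layers)
  expect_length(fit$loss_history, 0)
})

test_that("training is deterministic under a fixed seed", {
  fx <- make_training_fixture()
  for (arch in c("gcn", "gat")) {
    spec <- model_spec(arch, 6, 4, 3, heads = 2)
    cfg <- train_config(epochs = 25, seed = 11)
    f1 <- train(build_model(spec), fx$graph, fx$tbl, fx$train, cfg)
    f2 <- train(build_model(spec), fx$graph, fx$tbl, fx$train, cfg)
    expect_identical(f1$loss_history, f2$loss_history)
    expect_identical(f1$model$layers, f2$model$layers)
    f3 <- train(build_model(spec), fx$graph, fx$tbl, fx$train,
                train_config(epochs = 25, seed = 12))
    expect_false(identical(f3$loss_history, f1$loss_history))
  }
})

test_that("loss falls on separable data for all architectures", {
  fx <- make_training_fixture(n = 90, sep = 8)
  for (arch in c("gcn", "sage", "gat")) {
    fit <- train(build_model(model_spec(arch, 6, 8, 3, heads = 2)),
                 fx$graph, fx$tbl, fx$train,
                 train_config(epochs = 120, seed = 3))
    expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
    expect_true(all(is.finite(fit$loss_history)))
  }
})

test_that("predictions are softmax probabilities consistent with logits", {
  fx <- make_training_fixture()
  model <- build_model(model_spec("gcn", 6, 8, 3), seed = 5)
  probs <- predict(model, fx$graph, fx$tbl)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_true(all(probs > 0))

  # a zero model scores every class equally
  zero <- audiograph:::unflatten_params(
    model, numeric(count_parameters(model))
  )
  expect_equal(predict(zero, fx$graph, fx$tbl),
               matrix(1 / 3, nrow(fx$tbl), 3))

  # argmax of probabilities equals argmax of raw logits
  gctx <- audiograph:::graph_context(fx$graph, "gcn")
  logits <- audiograph:::model_forward(model, gctx,
                                       feature_matrix(fx$tbl))$logits
  expect_equal(predicted_labels(probs), predicted_labels(logits))
})

test_that("stronger weight decay shrinks the trained weights", {
  fx <- make_training_fixture(n = 80)
  norms <- vapply(c(0, 0.01, 0.2), function(wd) {
    fit <- train(build_model(model_spec("gcn", 6, 8, 3)), fx$graph, fx$tbl,
                 fx$train, train_config(epochs = 150, seed = 9,
                                        weight_decay = wd))
    sqrt(sum(audiograph:::flatten_params(fit$model)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("training rejects masks that miss a class or carry no labels", {
  fx <- make_training_fixture()
  y <- node_labels(fx$tbl)
  model <- build_model(model_spec("gcn", 6, 4, 3))
  only_two <- fx$train & y != 2L
  expect_error(
    train(model, fx$graph, fx$tbl, only_two, train_config(epochs = 1)),
    "every class"
  )
  expect_error(
    train(model, fx$graph, fx$tbl, rep(FALSE, nrow(fx$tbl)),
          train_config(epochs = 1)),
    "nonempty"
  )
})
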