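test_that("a small CSV loads with dense re-encoded labels and folds", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,label,fold,f0,f1",
    "r1,b,1,0.5,1.5",
    "r2,a,1,2.0,3.0",
    "r3,b,2,0.0,-1.0"
  ), path)
  tbl <- load_embedding_table(path)
  expect_s3_class(tbl, "embedding_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(n_features(tbl), 2)
  expect_equal(n_classes(tbl), 2)
  # lexicographic encoding: a -> 0, b -> 1; row order preserved
  expect_equal(node_labels(tbl), c(1L, 0L, 1L))
  expect_equal(class_names(tbl), c("a", "b"))
  expect_equal(tbl$fold, c(1L, 1L, 2L))
  expect_equal(unname(feature_matrix(tbl)[2, ]), c(2, 3))
})

test_that("a missing feature value is rejected naming the cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label,f0,f1", "r1,a,1.0,2.0", "r2,a,NA,0.5"), path)
  expect_error(load_embedding_table(path), "f0.*row 2|row 2.*f0")
})

test_that("embedding tables round-trip through csv and tsv", {
  tbl <- generate_embeddings(synthetic_spec(25, d = 4, n_classes = 3,
                                            class_sep = 3, n_folds = 5,
                                            seed = 9))
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_embedding_table(tbl, path)
    back <- load_embedding_table(path)
    expect_equal(as.data.frame(back), as.data.frame(tbl))
    expect_equal(class_names(back), class_names(tbl))
  }
})

test_that("table validation rejects malformed inputs", {
  base <- tibble::tibble(id = c("a", "b"), label = c("x", "y"),
                         f0 = c(1, 2))
  expect_error(as_embedding_table(dplyr::select(base, -id)), "id")
  expect_error(
    as_embedding_table(dplyr::mutate(base, f2 = 1)), # gap: f0, f2
    "contiguous"
  )
  expect_error(
    as_embedding_table(dplyr::mutate(base, f0 = c(1, NA))),
    "missing feature"
  )
  expect_error(
    as_embedding_table(dplyr::mutate(base, fold = c(1L, 3L))),
    "contiguous range"
  )
  # duplicated ids are permitted: they are segment rows of one recording
  expect_silent(as_embedding_table(dplyr::mutate(base, id = c("a", "a"),
                                                 label = c("x", "x"))))
})

test_that("segment averaging is the column mean, permutation-invariant", {
  expect_equal(average_segments(rbind(c(1, 2), c(3, 4))), c(2, 3))
  expect_equal(average_segments(matrix(c(5, 6, 7), 1)), c(5, 6, 7))
  row <- c(0.3, -1, 2)
  expect_equal(average_segments(matrix(row, 10, 3, byrow = TRUE)), row)
  set.seed(4)
  seg <- matrix(rnorm(21), 7, 3)
  expect_equal(average_segments(seg),
               average_segments(seg[sample(7), , drop = FALSE]))
  expect_error(average_segments(matrix(numeric(), 0, 3)), "empty")
})

test_that("collapse_segments averages rows sharing an id", {
  df <- tibble::tibble(
    id = c("a", "a", "b"), label = c("x", "x", "y"),
    split = c("train", "train", "test"),
    f0 = c(1, 3, 5), f1 = c(0, 2, 4)
  )
  tbl <- collapse_segments(as_embedding_table(df))
  expect_equal(nrow(tbl), 2)
  expect_equal(unname(feature_matrix(tbl)["a", ]), c(2, 1))
  expect_equal(unname(feature_matrix(tbl)["b", ]), c(5, 4))
  # disagreeing labels within an id are an error
  df$label <- c("x", "y", "y")
  expect_error(collapse_segments(as_embedding_table(df)), "disagree")
})

test_that("edge lists are 0-based sorted TSV and round-trip", {
  g <- symmetrize(graph_from_edges(2, rbind(c(2L, 1L))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  expect_equal(readLines(path), c("0\t1", "1\t0"))
  back <- read_edge_list(path, n_nodes = 2)
  expect_equal(back$edges, g$edges)

  empty <- graph_from_edges(3, matrix(integer(), 0, 2))
  write_edge_list(empty, path)
  expect_equal(readLines(path), character(0))
  expect_equal(nrow(read_edge_list(path, n_nodes = 3)$edges), 0)
})
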