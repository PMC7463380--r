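test_that("feature partitions have the prescribed sizes and cover all indices", {
  p10 <- partition_features(10L, 10L, seed = 1L)
  expect_length(p10, 10L)
  expect_true(all(lengths(p10) == 1L))

  p1 <- partition_features(7L, 1L, seed = 1L)
  expect_length(p1, 1L)
  expect_setequal(p1[[1L]], 1:7)

  # 1393 = 10 * 139 + 3: three subsets of 140, seven of 139
  p <- partition_features(1393L, 10L, seed = 42L)
  expect_equal(unname(sort(lengths(p), decreasing = TRUE)),
               c(rep(140L, 3L), rep(139L, 7L)))
  expect_setequal(unlist(p), 1:1393)
  expect_error(partition_features(5L, 6L), "between 1 and n")
})

test_that("rotation matrices are exactly block-diagonal with orthonormal blocks", {
  set.seed(2)
  x <- matrix(rnorm(60L * 12L), 60L, 12L)
  rot <- build_rotation(x, K = 4L, seed = 3L)
  S <- as.matrix(rot)
  off_block <- matrix(TRUE, 12L, 12L)
  for (idx in rot$partition) off_block[idx, idx] <- FALSE
  expect_true(all(S[off_block] == 0))
  # un-rotating with the transpose recovers the centred features
  centred <- x
  for (j in seq_along(rot$partition)) {
    idx <- rot$partition[[j]]
    centred[, idx] <- sweep(x[, idx, drop = FALSE], 2L, rot$centers[[j]])
  }
  xr <- apply_rotation(rot, x)
  expect_equal(max(abs(xr %*% t(S) - centred)), 0, tolerance = 1e-9)
})

test_that("PCA on axis-aligned data yields a signed permutation", {
  x <- make_axis_gaussian(2000L, sds = c(4, 1, 9, 2), seed = 5L)
  rot <- build_rotation(x, K = 1L, bootstrap_fraction = 1, replace = FALSE)
  S <- abs(as.matrix(rot))
  # every row and column is dominated by a single near-unit entry
  expect_true(all(apply(S, 1L, max) > 0.99))
  expect_true(all(apply(S, 2L, max) > 0.99))
  expect_equal(colSums(S > 0.99), rep(1L, 4L), ignore_attr = TRUE)
})

test_that("zero-variance subsets degrade to identity blocks with a warning", {
  x <- cbind(matrix(rnorm(40L), 20L, 2L), 1, 1)
  part <- list(1:2, 3:4)
  expect_warning(rot <- build_rotation(x, partition = part, seed = 1L),
                 "zero variance")
  expect_equal(rot$blocks[[2L]], diag(2L))
})

test_that("the default ensemble has L trees with matching rotations", {
  task <- make_gaussian_task(30L, 20L, shift = 1, seed = 7L)
  m <- rotation_forest(task$x, task$y, seed = 1L)
  expect_length(m$trees, 12L)
  expect_length(m$rotations, 12L)
  expect_equal(m$hyperparams$K, 10L)
  # unpruned trees interpolate a separable training set
  sep <- make_gaussian_task(30L, 10L, shift = 4, seed = 8L)
  m2 <- rotation_forest(sep$x, sep$y, seed = 2L)
  expect_equal(mean(predict(m2, sep$x) == sep$y), 1)
  expect_error(rotation_forest(task$x, rep(1L, nrow(task$x))),
               "single class")
})

test_that("confidences average tree probabilities and sum to one", {
  task <- make_gaussian_task(40L, 8L, shift = 0.8, seed = 3L)
  m <- rotation_forest(task$x, task$y, K = 4L, L = 6L, seed = 9L)
  set.seed(10)
  queries <- matrix(rnorm(50L * 8L), 50L, 8L)
  conf <- predict_confidence(m, queries)
  expect_equal(rowSums(conf), rep(1, 50L), tolerance = 1e-12)
  # per-tree averaging: recompute by hand from the member trees
  manual <- Reduce(`+`, lapply(seq_len(6L), function(i) {
    xr <- apply_rotation(m$rotations[[i]], queries)
    colnames(xr) <- paste0("f", seq_len(ncol(xr)))
    predict(m$trees[[i]], as.data.frame(xr), type = "prob")
  })) / 6
  expect_equal(unname(conf), unname(manual[, m$label_order]))
  # predicted labels are the argmax of the confidences
  expect_equal(predict(m, queries),
               factor(m$label_order[apply(conf, 1L, which.max)],
                      levels = m$label_order))
  expect_error(predict_confidence(m, queries[, 1:5]), "expects 8")
})

test_that("training and prediction are seed-deterministic", {
  task <- make_gaussian_task(25L, 10L, shift = 0.7, seed = 4L)
  m1 <- rotation_forest(task$x, task$y, seed = 123L)
  m2 <- rotation_forest(task$x, task$y, seed = 123L)
  q <- matrix(rnorm(20L * 10L), 20L, 10L)
  expect_identical(predict_confidence(m1, q), predict_confidence(m2, q))
  # a different master seed produces genuinely different rotations
  # (K < n so the PCA blocks are non-trivial)
  m4 <- rotation_forest(task$x, task$y, K = 3L, seed = 123L)
  m5 <- rotation_forest(task$x, task$y, K = 3L, seed = 124L)
  expect_false(identical(as.matrix(m4$rotations[[1L]]),
                         as.matrix(m5$rotations[[1L]])))
})

test_that("a degenerate ensemble reduces to a single reference tree", {
  task <- make_gaussian_task(40L, 6L, shift = 0.6, seed = 6L)
  m <- rotation_forest(task$x, task$y, K = 1L, L = 1L,
                       bootstrap_fraction = 1, replace = FALSE,
                       rotate = FALSE, seed = 5L)
  x <- task$x
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- as.data.frame(x)
  df$.y <- factor(task$y)
  ref <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2L, minbucket = 1L, cp = 0, xval = 0L,
                        maxcompete = 0L, maxsurrogate = 0L,
                        usesurrogate = 0L))
  q <- make_gaussian_task(30L, 6L, shift = 0.6, seed = 16L)$x
  colnames(q) <- paste0("f", seq_len(ncol(q)))
  ref_pred <- predict(ref, as.data.frame(q), type = "class")
  expect_equal(as.character(predict(m, q)), as.character(ref_pred))
})

test_that("rotation diversifies trees enough to beat a single tree", {
  # mean-shifted Gaussian classes: ensemble accuracy averaged over seeds
  # must exceed the single unrotated tree's
  accs <- vapply(1:10, function(s) {
    train <- make_gaussian_task(100L, 20L, shift = 0.5, seed = s)
    test <- make_gaussian_task(100L, 20L, shift = 0.5, seed = 1000L + s)
    m <- rotation_forest(train$x, train$y, seed = s)
    single <- rotation_forest(train$x, train$y, K = 1L, L = 1L,
                              bootstrap_fraction = 1, replace = FALSE,
                              rotate = FALSE, seed = s)
    c(forest = mean(predict(m, test$x) == test$y),
      tree = mean(predict(single, test$x) == test$y))
  }, c(forest = 0, tree = 0))
  expect_gt(mean(accs["forest", ]), mean(accs["tree", ]))
})

test_that("models survive serialization with identical predictions", {
  task <- make_gaussian_task(30L, 8L, shift = 0.8, seed = 2L)
  m <- rotation_forest(task$x, task$y, K = 4L, L = 3L, seed = 7L)
  path <- tempfile(fileext = ".rds")
  save_rotation_forest(m, path)
  back <- load_rotation_forest(path)
  q <- matrix(rnorm(15L * 8L), 15L, 8L)
  expect_identical(predict_confidence(m, q), predict_confidence(back, q))
  other <- tempfile(fileext = ".rds")
  saveRDS(1:3, other)
  expect_error(load_rotation_forest(other), "rotation_forest")
})
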