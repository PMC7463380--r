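test_that("confusion counts follow the interacting/non-interacting reading", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c1, list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  c2 <- confusion_counts(c(0, 1), c(1, 0))
  expect_equal(c2, list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))

  set.seed(20)
  yt <- rbinom(50, 1, 0.5)
  yp <- rbinom(50, 1, 0.5)
  cc <- confusion_counts(yt, yp)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 50L)
  # elementwise oracle
  expect_equal(cc$TP, sum(mapply(function(a, b) a == 1 && b == 1, yt, yp)))
  expect_equal(cc$FN, sum(mapply(function(a, b) a == 1 && b == 0, yt, yp)))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0.*or 1|must be 0")
})

test_that("threshold metrics evaluate their closed forms exactly", {
  perfect <- classification_metrics(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  sensitivity = 1, mcc = 1))
  m <- classification_metrics(list(TP = 3L, TN = 2L, FP = 1L, FN = 1L))
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$mcc, 5 / 12)

  suppressMessages(
    deg <- classification_metrics(list(TP = 0L, TN = 5L, FP = 0L, FN = 5L)))
  expect_true(is.nan(deg$precision))
  expect_equal(deg$accuracy, 0.5)
  expect_error(classification_metrics(list(TP = 0L, TN = 0L, FP = 0L,
                                           FN = 0L)), "zero")
})

test_that("ROC handles perfect, flat and random score vectors", {
  y <- c(1, 1, 0, 0)
  expect_equal(roc_curve(y, c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_curve(y, rep(0.5, 4))$auc, 0.5)
  expect_error(roc_curve(c(1, 1), c(0.1, 0.2)), "negative")
  expect_error(roc_curve(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("AUC equals the Mann-Whitney pair-counting statistic", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:200, 1L)
    y <- c(1, 0, rbinom(n - 2L, 1L, 0.4))  # both classes guaranteed
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(roc_curve(y, scores)$auc, brute_auc(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under label swap with score negation", {
  set.seed(8)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  expect_equal(roc_curve(y, s)$auc, roc_curve(1 - y, -s)$auc,
               tolerance = 1e-12)
})

test_that("PR area follows the average-precision step rule", {
  y <- c(1, 1, 0, 0)
  expect_equal(pr_curve(y, c(0.9, 0.8, 0.2, 0.1))$aupr, 1)
  # all-tied scores: single point at precision = positive fraction
  expect_equal(pr_curve(c(1, 0, 0, 0), rep(0.3, 4))$aupr, 0.25)
  expect_error(pr_curve(c(0, 0), c(0.1, 0.2)), "positive")

  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:60, 1L)
    y <- c(1, rbinom(n - 1L, 1L, 0.3))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(pr_curve(y, scores)$aupr, brute_aupr(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("curves agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- c(1, 0, rbinom(80, 1, 0.5))
  s <- rnorm(82)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_curve(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("metrics are invariant under sample permutation", {
  set.seed(9)
  y <- c(1, 0, rbinom(30, 1, 0.5))
  s <- rnorm(32)
  pred <- as.integer(s > 0)
  perm <- sample(32)
  expect_equal(classification_metrics(confusion_counts(y, pred)),
               classification_metrics(confusion_counts(y[perm], pred[perm])))
  expect_equal(roc_curve(y, s)$auc, roc_curve(y[perm], s[perm])$auc)
})

test_that("stratified folds partition the data with balanced classes", {
  set.seed(14)
  x <- matrix(rnorm(100 * 4), 100, 4)
  y <- rep(c(0L, 1L), 50)

  # constant-score classifier: every fold AUC is exactly 1/2
  constant_factory <- function(x_train, y_train, seed) {
    structure(list(), class = "constant_clf")
  }
  assign("predict.constant_clf",
         function(object, newdata, type = "prob", ...) {
           matrix(0.5, nrow(newdata), 2L, dimnames = list(NULL, c("0", "1")))
         }, envir = globalenv())
  on.exit(rm("predict.constant_clf", envir = globalenv()), add = TRUE)
  cv <- cross_validate(x, y, model_fun = constant_factory, k = 5L,
                       seed = 2L)
  expect_equal(cv$folds$n_test, rep(20L, 5L))
  expect_equal(cv$folds$TP + cv$folds$FN, rep(10L, 5L))  # 10 positives/fold
  expect_equal(cv$folds$auc, rep(0.5, 5L))

  # per-fold mean and population sd recomputed by hand
  expect_equal(cv$mean$accuracy, mean(cv$folds$accuracy), tolerance = 1e-12)
  expect_equal(cv$sd$accuracy,
               sqrt(mean((cv$folds$accuracy - mean(cv$folds$accuracy))^2)),
               tolerance = 1e-12)
  expect_error(cross_validate(x[1:6, ], c(1L, rep(0L, 5L)), k = 5L),
               "stratified")
})

test_that("cross-validation of a learning model improves on chance", {
  task <- make_gaussian_task(50L, 10L, shift = 1, seed = 21L)
  cv <- cross_validate(task$x, task$y,
                       model_fun = function(x, y, seed) {
                         rotation_forest(x, y, K = 5L, L = 4L, seed = seed)
                       },
                       k = 5L, seed = 3L)
  expect_gt(cv$mean$auc, 0.8)
  # every sample sits in exactly one test fold
  expect_equal(sum(cv$folds$n_test), 100L)
})

test_that("CV summaries format and write deterministically", {
  set.seed(30)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- rep(c(0L, 1L), 30)
  model_fun <- function(x, y, seed) rotation_forest(x, y, K = 2L, L = 2L,
                                                    seed = seed)
  cv <- cross_validate(x, y, model_fun = model_fun, k = 3L, seed = 5L)
  lines <- format_cv_summary(cv)
  expect_length(lines, 5L)  # header + 3 folds + average
  expect_match(lines[5L], "^Average\t")
  p1 <- tempfile(); p2 <- tempfile()
  write_cv_summary(cv, p1)
  write_cv_summary(cv, p2)
  expect_identical(readLines(p1), readLines(p2))
})
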