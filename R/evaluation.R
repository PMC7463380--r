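#' Confusion counts of a binary prediction
#'
#' Label 1 marks an interacting pair. TP counts interacting pairs
#' classified as interacting, TN non-interacting pairs classified as
#' non-interacting, FP non-interacting pairs classified as interacting
#' and FN interacting pairs classified as non-interacting.
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return A list with integer counts `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("length mismatch: %d true labels vs %d predictions",
                 length(y_true), length(y_pred)))
  }
  y_true <- as.integer(as.character(y_true))
  y_pred <- as.integer(as.character(y_pred))
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be 0 (non-interacting) or 1 (interacting)")
  }
  list(TP = sum(y_true == 1L & y_pred == 1L),
       TN = sum(y_true == 0L & y_pred == 0L),
       FP = sum(y_true == 0L & y_pred == 1L),
       FN = sum(y_true == 1L & y_pred == 0L))
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose
#' denominator vanishes is undefined for that fold and returned as `NaN`
#' with a note, rather than silently reported as zero, so degenerate
#' folds stay visible.
#'
#' @param counts a list from [confusion_counts()].
#' @return A list with `accuracy`, `precision`, `sensitivity`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0L) stop("confusion counts are all zero")
  ratio <- function(num, den, name) {
    if (den == 0) {
      message("metric '", name, "' is undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  mcc_den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  list(accuracy = (tp + tn) / total,
       precision = ratio(tp, tp + fp, "precision"),
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       mcc = if (mcc_den2 == 0) {
         message("metric 'mcc' is undefined (a marginal count is zero)")
         NaN
       } else {
         (tp * tn - fn * fp) / sqrt(mcc_den2)
       })
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the distinct score values (tied
#' scores collapse into one step) and reports the false/true positive
#' rates at each threshold plus the endpoints (0,0) and (1,1). The AUC is
#' the trapezoidal area, which equals the tie-adjusted Mann-Whitney
#' concordance probability.
#'
#' @param y_true 0/1 labels with at least one of each class.
#' @param scores real-valued scores, larger = more confidently positive.
#' @return A list with vectors `fpr`, `tpr` and scalar `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  y_true <- as.integer(as.character(y_true))
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0L, 1L)))
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L) stop("no positive labels: ROC is undefined")
  if (n_neg == 0L) stop("no negative labels: ROC is undefined")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  last <- cumsum(rle(s)$lengths)  # last index of each tied score group
  tp <- cumsum(y)[last]
  fp <- (seq_along(y) - cumsum(y))[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Precision-recall curve and AUPR
#'
#' Precision/recall pairs over the same grouped threshold sweep as
#' [roc_curve()]. The area uses the average-precision step rule
#' `sum_k (R_k - R_(k-1)) * P_k` rather than trapezoids, which are known
#' to overestimate area in PR space.
#'
#' @param y_true 0/1 labels with at least one positive.
#' @param scores real-valued scores.
#' @return A list with vectors `recall`, `precision` and scalar `aupr`.
#' @export
pr_curve <- function(y_true, scores) {
  y_true <- as.integer(as.character(y_true))
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0L, 1L)))
  n_pos <- sum(y_true == 1L)
  if (n_pos == 0L) stop("no positive labels: precision-recall is undefined")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  npred <- last
  recall <- tp / n_pos
  precision <- tp / npred
  aupr <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, aupr = aupr)
}

#' Stratified k-fold cross-validation
#'
#' Splits the labeled pairs into k folds (stratified by class by default,
#' which preserves the positive:negative balance per fold), trains a
#' model on k-1 folds and evaluates on the held-out fold. Count-based
#' metrics threshold the class-1 confidence at `threshold`; ROC and PR
#' curves use the raw confidence as score.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param model_fun `function(x_train, y_train, seed)` returning a
#'   fitted model whose `predict(model, newdata, type = "prob")` yields a
#'   probability matrix with a `"1"` column; the default trains a
#'   [rotation_forest()] with its standard settings (K = 10, L = 12, 75%
#'   bootstrap).
#' @param k number of folds (default 5).
#' @param seed seed controlling fold assignment and the per-fold model
#'   seeds.
#' @param stratified assign folds per class (default TRUE).
#' @param threshold class-1 confidence above which a pair is called
#'   interacting (default 0.5).
#' @return An object of class `cv_summary`: list with `folds` (data.frame
#'   of per-fold metrics and counts), `mean`, `sd` (population standard
#'   deviation over folds), `k`, `seed`.
#' @export
cross_validate <- function(x, y, model_fun = NULL, k = 5L, seed = 1L,
                           stratified = TRUE, threshold = 0.5) {
  x <- as.matrix(x)
  y <- as.integer(as.character(y))
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(x) < k) stop("fewer samples than folds")
  if (is.null(model_fun)) {
    model_fun <- function(x_train, y_train, seed) {
      rotation_forest(x_train, y_train, seed = seed)
    }
  }
  fold_of <- integer(length(y))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  if (stratified) {
    for (cls in c(1L, 0L)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop(sprintf(
          "class %d has %d sample(s); stratified %d-fold CV needs at least %d",
          cls, length(idx), k, k))
      }
      fold_of[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold_of[sample.int(length(y))] <- rep_len(seq_len(k), length(y))
  }
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    fold_seed <- (as.integer(seed) + 100L * f) %% .Machine$integer.max
    model <- model_fun(x[train, , drop = FALSE], y[train], fold_seed)
    prob <- stats::predict(model, x[test, , drop = FALSE], type = "prob")
    score <- prob[, "1"]
    pred <- as.integer(score >= threshold)
    counts <- confusion_counts(y[test], pred)
    m <- classification_metrics(counts)
    roc <- roc_curve(y[test], score)
    pr <- pr_curve(y[test], score)
    fold_rows[[f]] <- data.frame(
      fold = f, n_test = length(test),
      TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
      accuracy = m$accuracy, precision = m$precision,
      sensitivity = m$sensitivity, mcc = m$mcc,
      auc = roc$auc, aupr = pr$aupr)
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- c("accuracy", "precision", "sensitivity", "mcc",
                   "auc", "aupr")
  mu <- vapply(folds[metric_cols], mean, 0)
  # population standard deviation over the k folds
  sdev <- vapply(folds[metric_cols],
                 function(v) sqrt(mean((v - mean(v))^2)), 0)
  structure(list(folds = folds, mean = as.list(mu), sd = as.list(sdev),
                 k = k, seed = as.integer(seed), threshold = threshold,
                 stratified = stratified),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(format_cv_summary(x), sep = "\n")
  invisible(x)
}

#' Format a CV summary as a per-fold table
#'
#' One row per fold plus an `Average` row in `mean +/- sd` form;
#' accuracy, precision, sensitivity and MCC are reported in percent, AUC
#' and AUPR on their natural 0-1 scale.
#'
#' @param cv a `cv_summary`.
#' @return Character vector of TSV lines.
#' @export
format_cv_summary <- function(cv) {
  f <- cv$folds
  header <- paste("Fold", "Accuracy (%)", "Precision (%)",
                  "Sensitivity (%)", "MCC (%)", "AUC", "AUPR", sep = "\t")
  rows <- vapply(seq_len(nrow(f)), function(i) {
    paste(f$fold[i],
          sprintf("%.2f", 100 * f$accuracy[i]),
          sprintf("%.2f", 100 * f$precision[i]),
          sprintf("%.2f", 100 * f$sensitivity[i]),
          sprintf("%.2f", 100 * f$mcc[i]),
          sprintf("%.4f", f$auc[i]),
          sprintf("%.4f", f$aupr[i]), sep = "\t")
  }, "")
  avg <- paste("Average",
               sprintf("%.2f ± %.2f", 100 * cv$mean$accuracy,
                       100 * cv$sd$accuracy),
               sprintf("%.2f ± %.2f", 100 * cv$mean$precision,
                       100 * cv$sd$precision),
               sprintf("%.2f ± %.2f", 100 * cv$mean$sensitivity,
                       100 * cv$sd$sensitivity),
               sprintf("%.2f ± %.2f", 100 * cv$mean$mcc,
                       100 * cv$sd$mcc),
               sprintf("%.4f ± %.4f", cv$mean$auc, cv$sd$auc),
               sprintf("%.4f ± %.4f", cv$mean$aupr, cv$sd$aupr),
               sep = "\t")
  c(header, rows, avg)
}

#' Write a CV summary to disk
#'
#' Writes the per-fold TSV table of [format_cv_summary()]; the output is
#' a pure function of the CV result, so identical runs produce
#' byte-identical files.
#'
#' @param cv a `cv_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_summary <- function(cv, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(format_cv_summary(cv), con, useBytes = TRUE)
  invisible(path)
}
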