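#' Randomly partition feature indices into K subsets
#'
#' The rotation-forest construction starts by splitting the n features
#' into K disjoint subsets. When K does not divide n, the `n mod K`
#' remainder features are absorbed by enlarging that many subsets by one,
#' so sizes are `floor(n/K)` or `floor(n/K) + 1` and the subsets cover
#' every index exactly once.
#'
#' @param n number of features.
#' @param K number of subsets (1 <= K <= n).
#' @param seed integer seed for the random assignment.
#' @return A list of K integer vectors of feature indices.
#' @export
partition_features <- function(n, K, seed = 1L) {
  n <- as.integer(n); K <- as.integer(K)
  if (K < 1L || K > n) {
    stop(sprintf("K must be between 1 and n = %d, got %d", n, K))
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  base <- n %/% K
  rem <- n %% K
  sizes <- rep(base, K) + c(rep(1L, rem), rep(0L, K - rem))
  unname(split(perm, rep(seq_len(K), sizes)))
}

#' Fit one block-diagonal PCA rotation
#'
#' For each feature subset, `ceil(bootstrap_fraction * N)` training rows
#' are drawn (with replacement by default -- bootstrap semantics) and
#' principal component analysis is run on the drawn rows restricted to the
#' subset's columns, mean-centred, keeping all components. The per-subset
#' coefficient blocks sit on the diagonal of a sparse n x n rotation
#' matrix; every off-block entry is exactly zero. A subset whose bootstrap
#' sample has zero variance (common with sparse binary fingerprints)
#' degrades to an identity block with a warning rather than failing.
#'
#' @param x numeric training matrix (N x n).
#' @param K number of feature subsets.
#' @param bootstrap_fraction fraction of rows drawn per subset (default
#'   0.75).
#' @param seed integer seed.
#' @param replace draw rows with replacement (default TRUE). With
#'   `replace = FALSE` and `bootstrap_fraction = 1` the full training set
#'   is used as-is.
#' @param partition optional pre-computed feature partition; when `NULL`
#'   one is drawn from `seed`.
#' @return An object of class `rotation_matrix`: list with `partition`,
#'   `blocks` (one orthonormal coefficient matrix per subset), `centers`
#'   (per-subset column means used for centring) and `n`.
#' @export
build_rotation <- function(x, K = 10L, bootstrap_fraction = 0.75,
                           seed = 1L, replace = TRUE, partition = NULL) {
  x <- as.matrix(x)
  n <- ncol(x); N <- nrow(x)
  if (N < 2L) stop("need at least two training rows")
  if (is.null(partition)) partition <- partition_features(n, K, seed)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  blocks <- vector("list", length(partition))
  centers <- vector("list", length(partition))
  for (j in seq_along(partition)) {
    idx <- partition[[j]]
    if (bootstrap_fraction >= 1 && !replace) {
      rows <- seq_len(N)
    } else {
      rows <- sample.int(N, ceiling(bootstrap_fraction * N),
                         replace = replace)
    }
    sub <- x[rows, idx, drop = FALSE]
    mu <- colMeans(sub)
    cv <- stats::cov(sub)
    if (max(abs(cv)) < 1e-12) {
      warning(sprintf(
        "feature subset %d has zero variance in its bootstrap sample; using an identity block",
        j))
      blocks[[j]] <- diag(length(idx))
    } else {
      # eigen() always yields a full square orthonormal basis, even when
      # the sample covariance is rank-deficient.
      blocks[[j]] <- eigen(cv, symmetric = TRUE)$vectors
    }
    centers[[j]] <- mu
  }
  structure(list(partition = partition, blocks = blocks,
                 centers = centers, n = n),
            class = "rotation_matrix")
}

#' Assemble the full sparse rotation matrix
#'
#' Places each subset's coefficient block on the diagonal; rows and
#' columns follow the original feature order, so off-block entries are
#' exactly zero by construction.
#'
#' @param x a `rotation_matrix`.
#' @param ... unused.
#' @return A dense n x n numeric matrix.
#' @export
as.matrix.rotation_matrix <- function(x, ...) {
  S <- matrix(0, x$n, x$n)
  for (j in seq_along(x$partition)) {
    idx <- x$partition[[j]]
    S[idx, idx] <- x$blocks[[j]]
  }
  S
}

#' Apply a rotation to a feature matrix
#'
#' Centres each subset's columns with the means estimated at fit time and
#' multiplies by the subset's coefficient block; used identically at
#' training and prediction time. The block structure is exploited so the
#' dense n x n matrix is never formed.
#'
#' @param rotation a `rotation_matrix`.
#' @param x numeric matrix with `rotation$n` columns.
#' @return The rotated matrix, same shape as `x`.
#' @export
apply_rotation <- function(rotation, x) {
  x <- as.matrix(x)
  if (ncol(x) != rotation$n) {
    stop(sprintf("x has %d columns, rotation expects %d",
                 ncol(x), rotation$n))
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_along(rotation$partition)) {
    idx <- rotation$partition[[j]]
    centered <- sweep(x[, idx, drop = FALSE], 2L, rotation$centers[[j]])
    out[, idx] <- centered %*% rotation$blocks[[j]]
  }
  out
}

#' Fit a rotation forest classifier
#'
#' An ensemble of L unpruned decision trees, each trained on the full
#' training set after rotating it with its own block-diagonal PCA
#' rotation: the feature set is randomly split into K subsets, each subset
#' gets a PCA basis estimated on a 75% bootstrap of the rows, and the
#' per-subset bases form the sparse rotation matrix. The per-tree
#' rotations de-correlate the base learners while preserving all feature
#' information (each block is a full orthonormal basis), which is what
#' gives the ensemble its diversity.
#'
#' @param x numeric feature matrix (N x n).
#' @param y class labels (coerced to factor; at least two classes).
#' @param K number of feature subsets per tree (default 10).
#' @param L number of trees (default 12).
#' @param bootstrap_fraction row fraction for the per-subset PCA
#'   bootstraps (default 0.75).
#' @param seed master seed; tree i derives its own seed by a fixed
#'   affine scrambling of the master seed, so trees are independent yet
#'   reproducible.
#' @param rotate set `FALSE` to force identity rotations (diagnostic
#'   mode; with `L = 1` the model then equals a single plain decision
#'   tree).
#' @param replace passed to [build_rotation()].
#' @param control an [rpart::rpart.control()] for the base trees; the
#'   default grows unpruned trees (cp = 0, minsplit = 2) splitting on
#'   Gini impurity.
#' @return An object of class `rotation_forest` with elements `trees`,
#'   `rotations`, `label_order` and `hyperparams`.
#' @export
rotation_forest <- function(x, y, K = 10L, L = 12L,
                            bootstrap_fraction = 0.75, seed = 1L,
                            rotate = TRUE, replace = TRUE,
                            control = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nrow(x) != length(y)) stop("x and y disagree on the number of samples")
  if (nlevels(y) < 2L) {
    stop("training labels contain a single class ('",
         levels(y), "'); at least two are required")
  }
  if (is.null(control)) {
    control <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                                    xval = 0L, maxcompete = 0L,
                                    maxsurrogate = 0L, usesurrogate = 0L)
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  trees <- vector("list", L)
  rotations <- vector("list", L)
  for (i in seq_len(L)) {
    # scrambled so that nearby master seeds share no per-tree streams
    tree_seed <- (as.double(seed) * 1009 + i * 7919) %% .Machine$integer.max
    if (rotate) {
      rot <- build_rotation(x, K = K,
                            bootstrap_fraction = bootstrap_fraction,
                            seed = tree_seed, replace = replace)
    } else {
      rot <- structure(list(partition = list(seq_len(ncol(x))),
                            blocks = list(diag(ncol(x))),
                            centers = list(rep(0, ncol(x))),
                            n = ncol(x)),
                       class = "rotation_matrix")
    }
    xr <- apply_rotation(rot, x)
    colnames(xr) <- colnames(x)
    df <- as.data.frame(xr)
    df$.y <- y
    trees[[i]] <- rpart::rpart(.y ~ ., data = df, method = "class",
                               control = control)
    rotations[[i]] <- rot
  }
  structure(list(trees = trees, rotations = rotations,
                 label_order = levels(y),
                 hyperparams = list(K = K, L = L,
                                    bootstrap_fraction = bootstrap_fraction,
                                    seed = as.integer(seed),
                                    rotate = rotate, replace = replace,
                                    control = control)),
            class = "rotation_forest")
}

#' @export
print.rotation_forest <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf(
    "rotation_forest: %d trees, K = %d feature subsets, classes: %s\n",
    h$L, h$K, paste(x$label_order, collapse = ", ")))
  invisible(x)
}

#' Per-class confidences of a rotation forest
#'
#' Each query row is rotated with every tree's own rotation and scored by
#' that tree; the ensemble confidence for class j is the plain average of
#' the L per-tree class-j probabilities, so each row of the result is a
#' probability vector summing to one.
#'
#' @param model a [rotation_forest()] model.
#' @param x query feature matrix with the training column count.
#' @return Numeric matrix, one row per query, one column per class in
#'   `model$label_order`.
#' @export
predict_confidence <- function(model, x) {
  stopifnot(inherits(model, "rotation_forest"))
  x <- as.matrix(x)
  n <- model$rotations[[1L]]$n
  if (ncol(x) != n) {
    stop(sprintf("query has %d columns, model expects %d", ncol(x), n))
  }
  acc <- matrix(0, nrow(x), length(model$label_order),
                dimnames = list(NULL, model$label_order))
  for (i in seq_along(model$trees)) {
    xr <- apply_rotation(model$rotations[[i]], x)
    colnames(xr) <- paste0("f", seq_len(ncol(xr)))
    p <- stats::predict(model$trees[[i]], as.data.frame(xr), type = "prob")
    acc <- acc + p[, model$label_order, drop = FALSE]
  }
  acc / length(model$trees)
}

#' Predict class labels with a rotation forest
#'
#' Assigns each query the class with the greatest averaged confidence;
#' exact ties go to the earliest class in `label_order`.
#'
#' @param object a [rotation_forest()] model.
#' @param newdata query feature matrix.
#' @param type `"class"` (default) for labels, `"prob"` for the
#'   confidence matrix of [predict_confidence()].
#' @param ... unused.
#' @return A factor of predicted labels, or the confidence matrix.
#' @export
predict.rotation_forest <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  conf <- predict_confidence(object, newdata)
  if (type == "prob") return(conf)
  idx <- apply(conf, 1L, which.max)  # which.max: first maximum = tie rule
  factor(object$label_order[idx], levels = object$label_order)
}

#' Save / load a rotation forest
#'
#' Serialises the complete model (trees, rotation blocks, partitions,
#' hyperparameters, label order and seed) to one archive file; loading
#' restores bit-identical predictions.
#'
#' @param model a [rotation_forest()] model.
#' @param path archive path.
#' @return `path` invisibly, or the restored model.
#' @export
save_rotation_forest <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rotation_forest
#' @export
load_rotation_forest <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rotation_forest")) {
    stop("file does not contain a rotation_forest model: ", path)
  }
  model
}
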