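# Shared fixture builders. Everything is generated in code at test time;
# no data files ship with the tests.

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# A small dataset with known geometry: d x t grid, given positive pairs.
make_grid_dataset <- function(n_drugs, n_targets, positive_idx = NULL) {
  drugs <- sprintf("d%d", seq_len(n_drugs))
  targets <- sprintf("t%d", seq_len(n_targets))
  if (is.null(positive_idx)) {
    return(dti_dataset(drugs, targets))
  }
  pos <- data.frame(
    drug_id = drugs[(positive_idx - 1L) %/% n_targets + 1L],
    target_id = targets[(positive_idx - 1L) %% n_targets + 1L],
    stringsAsFactors = FALSE)
  dti_dataset(drugs, targets, pos)
}

# Bit string of length n with ones at `on` (1-based).
make_bitstring <- function(n, on = integer()) {
  bits <- rep("0", n)
  bits[on] <- "1"
  paste(bits, collapse = "")
}

# Axis-aligned Gaussian training data with distinct per-axis variances.
make_axis_gaussian <- function(n, sds, seed = 1) {
  set.seed(seed)
  sapply(sds, function(s) rnorm(n, sd = s))
}

# Two-class Gaussian classification task with mean-shifted classes.
make_gaussian_task <- function(n_per_class, p, shift = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, mean = -shift), ncol = p),
             matrix(rnorm(n_per_class * p, mean = shift), ncol = p))
  y <- rep(c(0L, 1L), each = n_per_class)
  list(x = x, y = y)
}

# Brute-force complex cross-correlation with symmetric reflection,
# independent of the compiled path (direct quadruple loop).
brute_xcorr <- function(x, kernel) {
  refl <- function(i, n) {
    p <- 2L * n
    i <- i %% p
    ifelse(i < n, i, p - 1L - i)
  }
  h <- (nrow(kernel) - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0 + 0i, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0 + 0i
      for (du in -h:h) {
        for (dv in -h:h) {
          acc <- acc + x[refl(r - 1L + du, nr) + 1L,
                         refl(c - 1L + dv, nc) + 1L] *
            kernel[du + h + 1L, dv + h + 1L]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# Mann-Whitney pair-counting AUC oracle (ties count one half).
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold-by-threshold average-precision oracle.
brute_aupr <- function(y, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  n_pos <- sum(y == 1)
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    recall <- tp / n_pos
    precision <- tp / sum(pred)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}
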