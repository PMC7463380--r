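#' Construct a drug-target interaction dataset
#'
#' A drug-target interaction network is modelled as a bipartite graph:
#' one node set for drugs, one for protein targets, and an edge for every
#' experimentally known interaction. Known interactions are the positive
#' pairs; every other drug-target combination is a candidate negative.
#'
#' @param drug_ids character vector of unique drug identifiers (order kept).
#' @param target_ids character vector of unique target identifiers.
#' @param positives two-column data.frame (or matrix) of interacting
#'   `(drug_id, target_id)` pairs. Duplicate rows are collapsed.
#'
#' @return An object of class `dti_dataset` with elements `drug_ids`,
#'   `target_ids` and `positives` (a data.frame with columns `drug_id`,
#'   `target_id`).
#' @export
dti_dataset <- function(drug_ids, target_ids, positives = NULL) {
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) stop("duplicated drug identifiers")
  if (anyDuplicated(target_ids)) stop("duplicated target identifiers")
  if (is.null(positives)) {
    positives <- data.frame(drug_id = character(), target_id = character(),
                            stringsAsFactors = FALSE)
  } else {
    positives <- as.data.frame(positives, stringsAsFactors = FALSE)
    names(positives) <- c("drug_id", "target_id")
    positives$drug_id <- as.character(positives$drug_id)
    positives$target_id <- as.character(positives$target_id)
    positives <- unique(positives)
    rownames(positives) <- NULL
  }
  bad_d <- setdiff(positives$drug_id, drug_ids)
  bad_t <- setdiff(positives$target_id, target_ids)
  if (length(bad_d) || length(bad_t)) {
    stop("interaction pairs reference unknown identifiers: ",
         paste(c(bad_d, bad_t), collapse = ", "))
  }
  structure(list(drug_ids = drug_ids, target_ids = target_ids,
                 positives = positives),
            class = "dti_dataset")
}

#' @export
print.dti_dataset <- function(x, ...) {
  s <- dataset_stats(x)
  cat(sprintf(
    "dti_dataset: %d drugs x %d targets, %d known interactions (%.2f%% of %d pairs)\n",
    s$n_drugs, s$n_targets, s$n_positives, 100 * s$positive_fraction,
    s$n_total_pairs))
  invisible(x)
}

#' Read a drug-target pair list
#'
#' Reads a two-column UTF-8 TSV of interacting pairs
#' (`drug_id<TAB>target_id`). Lines starting with `#` are ignored.
#' Identifier order is first-appearance order, so downstream indices are
#' stable. Duplicated lines are collapsed to one interaction with a
#' warning, as public pair lists commonly contain duplicates.
#'
#' @param path path to the pair-list file.
#' @return A [dti_dataset()].
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stop("pair list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(dti_dataset(character(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- lineno[which(nfield != 2L)[1L]]
    stop(sprintf("malformed pair list %s: line %d has %d column(s), expected 2",
                 path, bad, nfield[which(nfield != 2L)[1L]]))
  }
  drugs <- vapply(parts, `[[`, "", 1L)
  targets <- vapply(parts, `[[`, "", 2L)
  key <- paste(drugs, targets, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(sprintf("%s: %d duplicated pair line(s) collapsed", path, ndup))
    first <- !duplicated(key)
    drugs <- drugs[first]
    targets <- targets[first]
  }
  dti_dataset(unique(drugs), unique(targets),
              data.frame(drug_id = drugs, target_id = targets,
                         stringsAsFactors = FALSE))
}

#' Summary statistics of an interaction network
#'
#' For a bipartite network with `n_drugs` drugs and `n_targets` targets
#' there are `n_drugs * n_targets` possible pairs; the pairs not known to
#' interact are the candidate negatives used for negative sampling.
#'
#' @param ds a [dti_dataset()].
#' @return A list with `n_drugs`, `n_targets`, `n_positives`,
#'   `n_total_pairs`, `n_candidate_negatives` and `positive_fraction`.
#' @export
dataset_stats <- function(ds) {
  stopifnot(inherits(ds, "dti_dataset"))
  n_d <- length(ds$drug_ids)
  n_t <- length(ds$target_ids)
  n_p <- nrow(ds$positives)
  total <- n_d * n_t
  list(n_drugs = n_d,
       n_targets = n_t,
       n_positives = n_p,
       n_total_pairs = total,
       n_candidate_negatives = total - n_p,
       positive_fraction = if (total > 0) n_p / total else 0)
}

#' Balanced negative sampling on the interaction network
#'
#' Known interactions are vastly outnumbered by unobserved pairs (for a
#' typical enzyme network, thousands of positives against hundreds of
#' thousands of candidate negatives), so training sets are balanced by
#' sampling as many presumed non-interacting pairs as there are positives.
#' Sampling is uniform without replacement over all non-positive pairs and
#' fully determined by `seed`.
#'
#' @param ds a [dti_dataset()].
#' @param n number of negatives to draw; defaults to the number of
#'   positives (a balanced set).
#' @param seed integer seed controlling the draw.
#' @return An object of class `labeled_pairs`: a data.frame with columns
#'   `drug_id`, `target_id`, `label` (1 = interacting, 0 = sampled
#'   negative) and attribute `seed`. Positives come first, in dataset
#'   order.
#' @export
sample_negatives <- function(ds, n = NULL, seed = 1L) {
  stopifnot(inherits(ds, "dti_dataset"))
  s <- dataset_stats(ds)
  if (is.null(n)) n <- s$n_positives
  n <- as.integer(n)
  if (n > s$n_candidate_negatives) {
    stop(sprintf(
      "requested %d negatives but only %d non-interacting pairs are available",
      n, s$n_candidate_negatives))
  }
  # Positive pairs as 0-based linear indices of the n_drugs x n_targets grid
  di <- match(ds$positives$drug_id, ds$drug_ids) - 1L
  ti <- match(ds$positives$target_id, ds$target_ids) - 1L
  pos_idx <- di * s$n_targets + ti
  neg_pool <- setdiff(seq_len(s$n_total_pairs) - 1L, pos_idx)
  drawn <- integer(0)
  if (n > 0L) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    drawn <- sort(sample(neg_pool, n, replace = FALSE))
  }
  neg <- data.frame(
    drug_id = ds$drug_ids[drawn %/% s$n_targets + 1L],
    target_id = ds$target_ids[drawn %% s$n_targets + 1L],
    stringsAsFactors = FALSE)
  out <- rbind(
    cbind(ds$positives, label = rep(1L, s$n_positives)),
    cbind(neg, label = rep(0L, nrow(neg))))
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed),
            class = c("labeled_pairs", "data.frame"))
}

#' Write a labeled pair set as three-column TSV
#'
#' Serialises `(drug_id, target_id, label)` rows for audit; the companion
#' reader is [read_labeled_pairs()].
#'
#' @param pairs a `labeled_pairs` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_pairs <- function(pairs, path) {
  stopifnot(all(c("drug_id", "target_id", "label") %in% names(pairs)))
  utils::write.table(pairs[, c("drug_id", "target_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a labeled pair set written by [write_labeled_pairs()]
#'
#' @param path path to a three-column TSV (drug_id, target_id, label).
#' @return A `labeled_pairs` data.frame.
#' @export
read_labeled_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          col.names = c("drug_id", "target_id", "label"),
                          colClasses = c("character", "character", "integer"))
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(df, class = c("labeled_pairs", "data.frame"))
}

# RNG bookkeeping: seeded draws must not disturb the caller's RNG stream.
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
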