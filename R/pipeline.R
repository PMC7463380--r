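#' Assemble per-pair feature rows
#'
#' Each labeled drug-target pair becomes one feature row: the drug's
#' fingerprint bits followed by the target's GIST descriptor (with the
#' 881-bit PubChem scheme and the default 512-value descriptor, rows have
#' 1393 columns). Row order equals pair order. Any pair whose drug lacks
#' a fingerprint or whose target lacks a descriptor aborts the build with
#' a list of every missing identifier -- no partial tables.
#'
#' @param pairs a `labeled_pairs` data.frame from [sample_negatives()].
#' @param fingerprints matrix from [read_fingerprints()].
#' @param descriptors matrix from [extract_gist_batch()] or
#'   [read_gist()].
#' @return An object of class `pair_features`: list with `ids` (the pair
#'   data.frame), `x` (numeric feature matrix) and `labels` (0/1 integer
#'   vector).
#' @export
build_pair_features <- function(pairs, fingerprints, descriptors) {
  stopifnot(all(c("drug_id", "target_id", "label") %in% names(pairs)))
  miss_d <- setdiff(unique(pairs$drug_id), rownames(fingerprints))
  miss_t <- setdiff(unique(pairs$target_id), rownames(descriptors))
  if (length(miss_d) || length(miss_t)) {
    stop("incomplete feature coverage.",
         if (length(miss_d)) paste0(" Missing fingerprints: ",
                                    paste(miss_d, collapse = ", "), "."),
         if (length(miss_t)) paste0(" Missing descriptors: ",
                                    paste(miss_t, collapse = ", "), "."))
  }
  x <- cbind(fingerprints[pairs$drug_id, , drop = FALSE],
             descriptors[pairs$target_id, , drop = FALSE])
  rownames(x) <- NULL
  storage.mode(x) <- "double"
  structure(list(ids = pairs[, c("drug_id", "target_id")],
                 x = x, labels = as.integer(pairs$label),
                 n_drug_features = ncol(fingerprints),
                 n_target_features = ncol(descriptors)),
            class = "pair_features")
}

#' Configure an end-to-end experiment
#'
#' Collects every knob of the pipeline in one validated record. Either
#' point `pairs_file` / `fingerprint_file` / `pssm_dir` at existing data
#' in the package's standard formats, or supply `synthetic` (a
#' [synthetic_spec()]) to generate a benchmark on the fly.
#'
#' @param pairs_file,fingerprint_file,pssm_dir input paths (ignored when
#'   `synthetic` is given; PSSM files must end in `.pssm`).
#' @param synthetic optional [synthetic_spec()].
#' @param normalization PSSM normalization strategy (see
#'   [normalize_pssm()]).
#' @param grid GIST pooling grid (default `c(4, 4)`).
#' @param pooling GIST pooling mode (default `"magnitude"`).
#' @param n_scales,n_orientations,lambda0 filter-bank settings (see
#'   [gabor_filter_bank()]).
#' @param K,L,bootstrap_fraction rotation-forest hyperparameters
#'   (defaults 10, 12, 0.75).
#' @param k number of cross-validation folds (default 5).
#' @param stratified stratify CV folds by class (default TRUE).
#' @param seed master seed; all stage seeds derive from it by fixed
#'   offsets (negative sampling: seed + 1, cross-validation: seed + 2,
#'   synthetic generation: the seed itself).
#' @param outdir output directory for reports and artifacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(pairs_file = NULL, fingerprint_file = NULL,
                              pssm_dir = NULL, synthetic = NULL,
                              normalization = "logistic",
                              grid = c(4L, 4L), pooling = "magnitude",
                              n_scales = 4L, n_orientations = 8L,
                              lambda0 = 4,
                              K = 10L, L = 12L, bootstrap_fraction = 0.75,
                              k = 5L, stratified = TRUE,
                              seed = 1L, outdir = tempfile("dtigist_run")) {
  if (is.null(synthetic)) {
    if (is.null(pairs_file) || is.null(fingerprint_file) ||
        is.null(pssm_dir)) {
      stop("either supply pairs_file, fingerprint_file and pssm_dir, ",
           "or a synthetic spec")
    }
    for (p in c(pairs_file, fingerprint_file, pssm_dir)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  } else {
    stopifnot(inherits(synthetic, "synthetic_spec"))
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  structure(list(pairs_file = pairs_file,
                 fingerprint_file = fingerprint_file,
                 pssm_dir = pssm_dir, synthetic = synthetic,
                 normalization = normalization, grid = as.integer(grid),
                 pooling = pooling, n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 lambda0 = lambda0, K = as.integer(K), L = as.integer(L),
                 bootstrap_fraction = bootstrap_fraction,
                 k = as.integer(k), stratified = stratified,
                 seed = seed, outdir = outdir),
            class = "experiment_config")
}

#' Run the full prediction experiment
#'
#' Executes the whole protocol: load (or synthesize) the interaction
#' network, fingerprints and PSSMs; normalize each PSSM and extract its
#' GIST descriptor; draw a balanced labeled pair set; assemble pair
#' features; run stratified k-fold cross-validation of the rotation
#' forest; and write the per-fold report, summary table, config snapshot,
#' serialized fold models and a stage log under `config$outdir`. The
#' whole run is a deterministic function of the config (including its
#' seed), so repeated runs produce byte-identical summaries.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress (default TRUE).
#' @return The `cv_summary`, invisibly augmented with an `outputs`
#'   attribute listing the files written.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    if (verbose) message(line)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!is.null(config$synthetic)) {
    data_dir <- file.path(config$outdir, "data")
    gen <- run_stage("simulate",
                     generate_synthetic_data(config$synthetic, data_dir))
    pairs_file <- gen$pairs
    fingerprint_file <- gen$fingerprints
    pssm_dir <- gen$pssm_dir
    note("simulate", "synthetic benchmark written to %s", data_dir)
  } else {
    pairs_file <- config$pairs_file
    fingerprint_file <- config$fingerprint_file
    pssm_dir <- config$pssm_dir
  }

  interactions <- run_stage("load_pairs", read_pair_list(pairs_file))

  fps <- run_stage("load_fingerprints", read_fingerprints(fingerprint_file))
  note("load_fingerprints", "%d fingerprints x %d bits", nrow(fps), ncol(fps))

  pssm_files <- sort(list.files(pssm_dir, pattern = "\\.pssm$",
                                full.names = TRUE))
  pssms <- run_stage("load_pssms", lapply(pssm_files, read_pssm))
  note("load_pssms", "%d PSSM files parsed", length(pssms))

  # The candidate universe is every drug with a fingerprint crossed with
  # every target with a PSSM; the pair list contributes the known
  # interactions. Drugs/targets without any known interaction therefore
  # still feed the negative pool.
  ds <- run_stage("build_network",
                  dti_dataset(rownames(fps),
                              vapply(pssms, function(p) p$protein_id, ""),
                              interactions$positives))
  s <- dataset_stats(ds)
  note("build_network", "%d drugs x %d targets, %d positives (%d candidate negatives)",
       s$n_drugs, s$n_targets, s$n_positives, s$n_candidate_negatives)

  bank <- gabor_filter_bank(n_scales = config$n_scales,
                            n_orientations = config$n_orientations,
                            lambda0 = config$lambda0)
  desc <- run_stage("gist",
                    extract_gist_batch(pssms, bank,
                                       normalization = config$normalization,
                                       grid = config$grid,
                                       pooling = config$pooling))
  note("gist", "%d descriptors x %d values (%d filters, %dx%d grid)",
       nrow(desc), ncol(desc), length(bank$filters),
       config$grid[1L], config$grid[2L])

  lp <- run_stage("sample_negatives",
                  sample_negatives(ds, seed = config$seed + 1L))
  note("sample_negatives", "%d labeled pairs (%d positive, %d negative)",
       nrow(lp), sum(lp$label == 1L), sum(lp$label == 0L))

  feats <- run_stage("build_features", build_pair_features(lp, fps, desc))
  note("build_features", "feature table %d x %d (drug block %d + target block %d)",
       nrow(feats$x), ncol(feats$x), feats$n_drug_features,
       feats$n_target_features)

  models <- list()
  model_fun <- function(x_train, y_train, fold_seed) {
    m <- rotation_forest(x_train, y_train, K = config$K, L = config$L,
                         bootstrap_fraction = config$bootstrap_fraction,
                         seed = fold_seed)
    models[[length(models) + 1L]] <<- m
    m
  }
  cv <- run_stage("cross_validate",
                  cross_validate(feats$x, feats$labels,
                                 model_fun = model_fun, k = config$k,
                                 seed = config$seed + 2L,
                                 stratified = config$stratified))
  note("cross_validate", "%d folds: mean accuracy %.4f, AUC %.4f, AUPR %.4f",
       cv$k, cv$mean$accuracy, cv$mean$auc, cv$mean$aupr)

  outputs <- c(
    summary = write_cv_summary(cv, file.path(config$outdir,
                                             "cv_summary.tsv")),
    labeled_pairs = write_labeled_pairs(lp, file.path(config$outdir,
                                                      "labeled_pairs.tsv")),
    descriptors = write_gist(desc, file.path(config$outdir,
                                             "gist_descriptors.tsv")))
  folds_path <- file.path(config$outdir, "cv_folds.tsv")
  utils::write.table(cv$folds, folds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, folds = folds_path)
  model_dir <- file.path(config$outdir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  for (i in seq_along(models)) {
    save_rotation_forest(models[[i]],
                         file.path(model_dir, sprintf("fold%02d.rds", i)))
  }
  snap <- config
  snap$synthetic <- if (is.null(config$synthetic)) NULL else
    unclass(config$synthetic)
  cfg_path <- file.path(config$outdir, "config.json")
  jsonlite::write_json(unclass(snap), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  outputs <- c(outputs, config = cfg_path)
  log_path <- file.path(config$outdir, "run.log")
  writeLines(log_lines, log_path)
  outputs <- c(outputs, log = log_path)

  attr(cv, "outputs") <- outputs
  invisible(cv)
}
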