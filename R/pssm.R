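#' @useDynLib dtigist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# PSI-BLAST's native amino-acid column order.
PSSM_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Construct a PSSM object
#'
#' A position-specific scoring matrix is the evolutionary profile of one
#' protein: row n holds the 20 log-odds substitution scores of sequence
#' position n against the standard amino acids, in PSI-BLAST column order
#' `ARNDCQEGHILKMFPSTWYV`. Scores are integers as printed by PSI-BLAST.
#'
#' @param protein_id protein identifier.
#' @param sequence amino-acid string of length M.
#' @param scores M x 20 integer matrix of log-odds scores.
#' @return An object of class `pssm`.
#' @export
pssm <- function(protein_id, sequence, scores) {
  sequence <- as.character(sequence)
  scores <- as.matrix(scores)
  m <- nchar(sequence)
  if (m < 1L) stop("sequence must have at least one residue")
  if (nrow(scores) != m || ncol(scores) != 20L) {
    stop(sprintf("scores must be %d x 20 for a %d-residue sequence, got %d x %d",
                 m, m, nrow(scores), ncol(scores)))
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(NULL, PSSM_ALPHABET)
  structure(list(protein_id = as.character(protein_id),
                 sequence = sequence, scores = scores),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm '%s': %d residues x 20 amino acids (scores %d..%d)\n",
              x$protein_id, nrow(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard `-out_ascii_pssm` layout: header lines, then one row
#' per residue carrying the position index, the residue letter, 20 integer
#' log-odds scores, 20 integer weighted-percentage columns and two
#' trailing reals. Only the log-odds block is retained (the standard
#' "evolutionary information" reading); the sequence is reconstructed from
#' the residue-letter column.
#'
#' @param path path to the ASCII PSSM file.
#' @param protein_id identifier to attach; defaults to the file base name.
#' @return A [pssm()] object.
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  # Header: the line listing the amino-acid column letters (20 repeated twice)
  header <- which(vapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    length(toks) %in% c(20L, 40L) && all(toks %in% PSSM_ALPHABET)
  }, logical(1), USE.NAMES = FALSE))
  if (!length(header)) {
    stop("not a PSI-BLAST ASCII PSSM (no amino-acid header line): ", path)
  }
  start <- header[1L] + 1L
  residues <- character()
  rows <- list()
  for (i in start:length(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) break
    toks <- strsplit(l, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", toks[1L])) break
    if (length(toks) != 44L) {
      stop(sprintf("%s: line %d has %d fields, expected 44 (pos, residue, 20+20 scores, 2 reals)",
                   path, i, length(toks)))
    }
    sc <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(sc)) {
      stop(sprintf("%s: line %d has a non-integer log-odds score", path, i))
    }
    residues <- c(residues, toks[2L])
    rows[[length(rows) + 1L]] <- sc
  }
  if (!length(rows)) stop("no residue rows found in PSSM file: ", path)
  pssm(protein_id, paste(residues, collapse = ""),
       do.call(rbind, rows))
}

#' Write a PSSM in the PSI-BLAST ASCII layout
#'
#' Emits a file that [read_pssm()] parses back to an identical score
#' matrix and sequence. The weighted-percentage block and the two trailing
#' per-row reals carry no information used by this package, so they are
#' filled with zeros.
#'
#' @param p a [pssm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  m <- nrow(p$scores)
  res <- strsplit(p$sequence, "")[[1]]
  head1 <- ""
  head2 <- "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"
  head3 <- paste0(strrep(" ", 11),
                  paste(sprintf("%3s", rep(PSSM_ALPHABET, 2L)), collapse = ""))
  body <- vapply(seq_len(m), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%4d", p$scores[i, ]), collapse = ""),
           paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, "")
  writeLines(c(head1, head2, head3, body, ""), path)
  invisible(path)
}

#' Normalize a PSSM before texture filtering
#'
#' Log-odds scores are signed integers of unbounded range; filtering them
#' directly would make Gabor responses depend on the score scale. The
#' default squashes each entry through the logistic map
#' `1 / (1 + exp(-x))`, the dominant convention in the PSSM-feature
#' literature: it is strictly monotone, bounded in (0,1) and maps 0 to
#' 0.5. `"minmax"` rescales linearly to \[0,1\] per protein and `"none"`
#' passes raw scores through for sensitivity studies.
#'
#' @param p a [pssm()] object.
#' @param method `"logistic"` (default), `"minmax"` or `"none"`.
#' @return An object of class `pssm_profile`: list with `protein_id` and
#'   `values`, an M x 20 numeric matrix.
#' @export
normalize_pssm <- function(p, method = c("logistic", "minmax", "none")) {
  stopifnot(inherits(p, "pssm"))
  method <- match.arg(method)
  x <- p$scores
  storage.mode(x) <- "double"
  values <- switch(method,
    logistic = 1 / (1 + exp(-x)),
    minmax = {
      rng <- range(x)
      if (rng[1] == rng[2]) matrix(0.5, nrow(x), ncol(x),
                                   dimnames = dimnames(x))
      else (x - rng[1]) / (rng[2] - rng[1])
    },
    none = x)
  structure(list(protein_id = p$protein_id, values = values),
            class = "pssm_profile")
}

#' Synthesize a PSSM with a realistic per-residue structure
#'
#' Draws a random amino-acid sequence over the 20 standard residues and
#' builds integer scores from a per-residue base profile -- a high score
#' (+6) on the residue's own column and a mildly negative score (-2)
#' elsewhere, mimicking the conserved-position pattern of real profiles --
#' plus rounded Gaussian noise of standard deviation `noise_scale`.
#' Deterministic for a fixed seed.
#'
#' @param protein_id identifier for the synthetic protein.
#' @param length sequence length M; at least 4 so the 4x4 descriptor grid
#'   has a non-empty row band per protein.
#' @param seed integer seed.
#' @param noise_scale standard deviation of the integer score noise
#'   (>= 0).
#' @param band_bias optional numeric vector of length 4: an integer-rounded
#'   offset added to all scores in the corresponding quarter of the rows,
#'   used by the synthetic-data generator to plant grid-recoverable
#'   signal. Default no bias.
#' @return A [pssm()] object.
#' @export
synthesize_pssm <- function(protein_id, length, seed = 1L, noise_scale = 2,
                            band_bias = NULL) {
  length <- as.integer(length)
  if (length < 4L) {
    stop("length must be >= 4: the 4x4 GIST grid needs one row per band")
  }
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  residues <- sample(PSSM_ALPHABET, length, replace = TRUE)
  base <- matrix(-2L, length, 20L)
  base[cbind(seq_len(length), match(residues, PSSM_ALPHABET))] <- 6L
  noise <- matrix(as.integer(round(stats::rnorm(length * 20L,
                                                sd = noise_scale))),
                  length, 20L)
  scores <- base + noise
  if (!is.null(band_bias)) {
    stopifnot(length(band_bias) == 4L)
    bands <- .grid_bands(length, 4L)
    for (b in seq_len(4L)) {
      rows <- bands[[b]]
      scores[rows, ] <- scores[rows, ] + as.integer(round(band_bias[b]))
    }
  }
  pssm(protein_id, paste(residues, collapse = ""), scores)
}

#' Generate a PSSM by running PSI-BLAST
#'
#' Thin wrapper around the `psiblast` executable: runs the iterative
#' profile search with an e-value inclusion threshold of 0.001 and 3
#' iterations (other parameters at tool defaults) and parses the ASCII
#' PSSM it writes. Requires a local PSI-BLAST installation and a formatted
#' protein database.
#'
#' @param sequence_file single-record protein FASTA query.
#' @param database_path path prefix of a formatted BLAST protein database.
#' @param out_pssm_path where the ASCII PSSM is written.
#' @param evalue inclusion e-value threshold (default 0.001).
#' @param iterations number of PSI-BLAST iterations (default 3).
#' @param psiblast name or path of the executable.
#' @return A [pssm()] object parsed from the run's output.
#' @export
run_psiblast <- function(sequence_file, database_path, out_pssm_path,
                         evalue = 0.001, iterations = 3L,
                         psiblast = "psiblast") {
  if (!file.exists(sequence_file)) {
    stop("query FASTA not found: ", sequence_file)
  }
  fasta <- readLines(sequence_file, warn = FALSE)
  fasta <- fasta[nzchar(trimws(fasta))]
  if (!length(fasta) || !startsWith(fasta[1L], ">")) {
    stop("malformed FASTA (first record must start with '>'): ",
         sequence_file)
  }
  seq_lines <- fasta[-1L]
  if (!length(seq_lines) || any(grepl("[^A-Za-z*]", seq_lines))) {
    stop("malformed FASTA (empty or non-residue sequence body): ",
         sequence_file)
  }
  exe <- Sys.which(psiblast)
  if (!nzchar(exe)) {
    stop("PSI-BLAST executable '", psiblast, "' not found on PATH; ",
         "install NCBI BLAST+ or pass its location via `psiblast=`")
  }
  if (!any(file.exists(paste0(database_path,
                              c("", ".pin", ".phr", ".psq", ".pdb"))))) {
    stop("no formatted BLAST database at: ", database_path)
  }
  args <- c("-query", shQuote(sequence_file),
            "-db", shQuote(database_path),
            "-evalue", format(evalue),
            "-num_iterations", as.integer(iterations),
            "-out_ascii_pssm", shQuote(out_pssm_path))
  status <- system2(exe, args, stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L) {
    stop("psiblast exited with status ", code, ":\n",
         paste(status, collapse = "\n"))
  }
  if (!file.exists(out_pssm_path)) {
    stop("psiblast completed but wrote no PSSM (query may have no hits)")
  }
  read_pssm(out_pssm_path)
}

# Half-open row bands [floor(b*M/k), floor((b+1)*M/k)) as 1-based indices;
# a partition of 1..M for every M >= k.
.grid_bands <- function(m, k) {
  lapply(seq_len(k), function(b) {
    lo <- floor((b - 1L) * m / k) + 1L
    hi <- floor(b * m / k)
    seq.int(lo, hi)
  })
}
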