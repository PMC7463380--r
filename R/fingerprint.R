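#' Read 881-bit drug substructure fingerprints
#'
#' Each drug molecule is described by the PubChem substructure fingerprint:
#' a fixed dictionary of 881 chemical fragments, with bit k set to 1 when
#' fragment k occurs in the molecule. The on-disk dialect is a UTF-8 TSV
#' with columns `drug_id<TAB>bitstring`, the bitstring being 881 characters
#' of `0`/`1` (bit index 1 = first character). `#` comment lines are
#' ignored.
#'
#' @param path path to the fingerprint file.
#' @param n_bits expected fingerprint length (881 for the PubChem scheme).
#' @return An integer matrix with one row per drug (rownames = drug ids)
#'   and `n_bits` columns of 0/1 values.
#' @export
read_fingerprints <- function(path, n_bits = 881L) {
  if (!file.exists(path)) stop("fingerprint file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    m <- matrix(integer(), nrow = 0, ncol = n_bits)
    return(m)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed fingerprint file: each line must be drug_id<TAB>bitstring")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  bitstr <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids)) {
    stop("duplicated drug identifiers in fingerprint file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(bitstr)
  if (any(lens != n_bits)) {
    i <- which(lens != n_bits)[1L]
    stop(sprintf("fingerprint for drug '%s' has length %d, expected %d",
                 ids[i], lens[i], n_bits))
  }
  bad <- grepl("[^01]", bitstr)
  if (any(bad)) {
    stop(sprintf("fingerprint for drug '%s' contains characters outside {0,1}",
                 ids[which(bad)[1L]]))
  }
  bits <- matrix(as.integer(unlist(strsplit(bitstr, "", fixed = TRUE))),
                 nrow = length(ids), ncol = n_bits, byrow = TRUE)
  rownames(bits) <- ids
  bits
}

#' Write fingerprints in the TSV bitstring dialect
#'
#' Inverse of [read_fingerprints()]: writing then reading reproduces the
#' bit matrix exactly.
#'
#' @param fingerprints 0/1 integer matrix with drug ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  stopifnot(is.matrix(fingerprints), !is.null(rownames(fingerprints)))
  if (!all(fingerprints %in% c(0L, 1L))) stop("fingerprint bits must be 0/1")
  lines <- vapply(seq_len(nrow(fingerprints)), function(i) {
    paste0(rownames(fingerprints)[i], "\t",
           paste(fingerprints[i, ], collapse = ""))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Fingerprint feature block of one drug
#'
#' The classifier consumes the fingerprint bits directly as the drug's
#' feature block, order preserved: the mapping from bits to features is a
#' bijection, so no structural information is lost.
#'
#' @param fingerprints matrix from [read_fingerprints()].
#' @param drug_id drug identifier (row name).
#' @return Numeric vector of length `ncol(fingerprints)`.
#' @export
fingerprint_features <- function(fingerprints, drug_id) {
  if (!drug_id %in% rownames(fingerprints)) {
    stop("no fingerprint for drug: ", drug_id)
  }
  as.numeric(fingerprints[drug_id, ])
}
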