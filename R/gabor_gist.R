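#' Gabor filter parameters
#'
#' A 2-D Gabor filter is a Gaussian envelope modulated by a complex
#' sinusoidal plane wave. In rotated coordinates
#' `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`
#' the kernel is
#' `G(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * exp(i (2 pi x' / lambda + psi))`.
#'
#' @param lambda wavelength of the sinusoid, in pixels (> 0).
#' @param theta orientation of the parallel stripes, radians.
#' @param psi phase shift, radians (default 0).
#' @param gamma spatial aspect ratio of the Gaussian envelope (default
#'   0.5, the conventional elongated envelope).
#' @param sigma standard deviation of the Gaussian envelope, pixels;
#'   default `0.56 * lambda`, the usual half-octave bandwidth coupling.
#' @param halfwidth kernel half-width in pixels; the sampled kernel is a
#'   `(2*halfwidth+1)` square. Default `ceiling(3 * sigma)` so the
#'   envelope is captured to three standard deviations.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(lambda, theta, psi = 0, gamma = 0.5,
                         sigma = 0.56 * lambda,
                         halfwidth = ceiling(3 * sigma)) {
  stopifnot(lambda > 0, sigma > 0, gamma > 0, halfwidth >= 1)
  structure(list(lambda = lambda, theta = theta, psi = psi, gamma = gamma,
                 sigma = sigma, halfwidth = as.integer(halfwidth)),
            class = "gabor_params")
}

#' Evaluate the complex Gabor kernel at one pixel offset
#'
#' @param x,y pixel offsets from the kernel centre.
#' @param params a [gabor_params()] object.
#' @return A complex value; its real and imaginary parts are the
#'   cosine- and sine-phase filter components.
#' @export
gabor_kernel_value <- function(x, y, params) {
  xp <- x * cos(params$theta) + y * sin(params$theta)
  yp <- -x * sin(params$theta) + y * cos(params$theta)
  envelope <- exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$sigma^2))
  phase <- 2 * pi * xp / params$lambda + params$psi
  complex(real = envelope * cos(phase), imaginary = envelope * sin(phase))
}

#' Sample a Gabor kernel on its square pixel grid
#'
#' @param params a [gabor_params()] object.
#' @return A complex matrix of side `2*halfwidth + 1`; entry `[i, j]`
#'   holds the kernel at offset `(x, y) = (i - h - 1, j - h - 1)` (first
#'   index = x).
#' @export
gabor_kernel <- function(params) {
  h <- params$halfwidth
  offs <- seq.int(-h, h)
  outer(offs, offs, function(x, y) gabor_kernel_value(x, y, params))
}

#' Build the Gabor filter bank
#'
#' The default bank has 4 scales x 8 orientations = 32 filters, the
#' configuration used for PSSM texture extraction. Orientation o has
#' `theta = (o-1) * pi / n_orientations` (a half-turn suffices because
#' orientations theta and theta+pi give mirrored responses); scale s has
#' wavelength `lambda0 * 2^(s-1)` (octave spacing) with the envelope tied
#' to the wavelength via `sigma = 0.56 * lambda`. Filters are ordered
#' scale-major, then orientation.
#'
#' @param n_scales number of scales (default 4).
#' @param n_orientations number of orientations (default 8).
#' @param lambda0 base wavelength in pixels (default 4).
#' @param psi phase shift shared by all filters (default 0).
#' @param gamma shared aspect ratio (default 0.5).
#' @return An object of class `gabor_bank`: list of filters, each with
#'   elements `scale`, `orientation`, `params` and `kernel` (complex
#'   matrix).
#' @export
gabor_filter_bank <- function(n_scales = 4L, n_orientations = 8L,
                              lambda0 = 4, psi = 0, gamma = 0.5) {
  stopifnot(n_scales >= 1L, n_orientations >= 1L)
  filters <- list()
  for (s in seq_len(n_scales)) {
    lambda <- lambda0 * 2^(s - 1)
    for (o in seq_len(n_orientations)) {
      p <- gabor_params(lambda = lambda,
                        theta = (o - 1) * pi / n_orientations,
                        psi = psi, gamma = gamma)
      filters[[length(filters) + 1L]] <-
        list(scale = s, orientation = o, params = p,
             kernel = gabor_kernel(p))
    }
  }
  structure(list(filters = filters, n_scales = n_scales,
                 n_orientations = n_orientations),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("gabor_bank: %d filters (%d scales x %d orientations)\n",
              length(x$filters), x$n_scales, x$n_orientations))
  invisible(x)
}

#' Filter a normalized profile with a Gabor bank
#'
#' Correlates the M x 20 profile with every kernel of the bank in the
#' spatial domain (correlation, i.e. no kernel flip; at psi = 0 the real
#' part is even so only the odd sine component feels the difference).
#' Borders are handled by symmetric reflection of the profile, so the
#' response has the same M x 20 shape.
#'
#' @param profile a `pssm_profile` from [normalize_pssm()], or a plain
#'   numeric matrix with at least 4 rows.
#' @param bank a [gabor_filter_bank()].
#' @param output `"magnitude"` (default) for the complex modulus of the
#'   response, `"real"` or `"imaginary"` for a single phase component.
#' @return A list of response matrices, one per filter, each the shape of
#'   the profile.
#' @export
filter_response <- function(profile, bank,
                            output = c("magnitude", "real", "imaginary")) {
  output <- match.arg(output)
  x <- if (inherits(profile, "pssm_profile")) profile$values else profile
  x <- as.matrix(x)
  if (nrow(x) < 4L) {
    stop(sprintf("profile has %d row(s); at least 4 are required", nrow(x)))
  }
  lapply(bank$filters, function(f) {
    res <- .xcorr2_reflect(x, Re(f$kernel), Im(f$kernel))
    switch(output,
           magnitude = sqrt(res$re^2 + res$im^2),
           real = res$re,
           imaginary = res$im)
  })
}

#' Extract the block-GIST descriptor of a profile
#'
#' The profile (an M x 20 image) is filtered with every kernel in the
#' bank; each response map is divided into a `grid[1] x grid[2]` grid of
#' contiguous blocks and each block is summarised by its mean response.
#' With the default 4 x 4 grid and 32-filter bank this yields the
#' 512-dimensional descriptor (16 blocks x 32 filters). Ordering is
#' filter-major, blocks row-major within a filter. Row band b covers rows
#' `[floor((b-1) M / 4), floor(b M / 4))`, a partition for any M >= 4;
#' the 20 columns split into 4 bands of 5.
#'
#' @param profile a `pssm_profile` or numeric matrix (M >= grid rows).
#' @param bank a [gabor_filter_bank()].
#' @param grid integer pair `(rows, cols)` of the pooling grid (default
#'   `c(4, 4)`).
#' @param pooling passed to [filter_response()] as `output`; the default
#'   magnitude pooling makes every descriptor entry non-negative.
#' @return An object of class `gist_descriptor`: list with `protein_id`,
#'   `values` (numeric vector of length `prod(grid) * n_filters`) and
#'   `grid`.
#' @export
extract_gist <- function(profile, bank, grid = c(4L, 4L),
                         pooling = c("magnitude", "real", "imaginary")) {
  pooling <- match.arg(pooling)
  pid <- if (inherits(profile, "pssm_profile")) profile$protein_id else NA_character_
  x <- if (inherits(profile, "pssm_profile")) profile$values else as.matrix(profile)
  if (nrow(x) < grid[1L]) {
    stop(sprintf("profile has %d row(s); the %dx%d grid needs at least %d",
                 nrow(x), grid[1L], grid[2L], grid[1L]))
  }
  responses <- filter_response(x, bank, output = pooling)
  rbands <- .grid_bands(nrow(x), grid[1L])
  cbands <- .grid_bands(ncol(x), grid[2L])
  values <- unlist(lapply(responses, function(map) {
    vapply(seq_len(grid[1L]), function(r) {
      vapply(seq_len(grid[2L]), function(c) {
        mean(map[rbands[[r]], cbands[[c]]])
      }, 0)
    }, numeric(grid[2L]))
  }), use.names = FALSE)
  structure(list(protein_id = pid, values = values, grid = grid),
            class = "gist_descriptor")
}

#' Batch-extract GIST descriptors from PSSMs
#'
#' Normalizes each PSSM and extracts its descriptor; the workhorse behind
#' the command-line `gist` subcommand.
#'
#' @param pssms list of [pssm()] objects.
#' @param bank a [gabor_filter_bank()]; built with defaults when `NULL`.
#' @param normalization passed to [normalize_pssm()].
#' @param grid,pooling passed to [extract_gist()].
#' @return A numeric matrix, one row per protein (rownames = protein
#'   ids).
#' @export
extract_gist_batch <- function(pssms, bank = NULL,
                               normalization = "logistic",
                               grid = c(4L, 4L), pooling = "magnitude") {
  if (is.null(bank)) bank <- gabor_filter_bank()
  rows <- lapply(pssms, function(p) {
    extract_gist(normalize_pssm(p, normalization), bank, grid, pooling)$values
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(pssms, function(p) p$protein_id, "")
  out
}

#' Write GIST descriptors as TSV
#'
#' One row per protein: the identifier followed by the descriptor values.
#'
#' @param descriptors matrix from [extract_gist_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gist <- function(descriptors, path) {
  stopifnot(is.matrix(descriptors), !is.null(rownames(descriptors)))
  lines <- vapply(seq_len(nrow(descriptors)), function(i) {
    paste(c(rownames(descriptors)[i],
            sprintf("%.10g", descriptors[i, ])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read GIST descriptors written by [write_gist()]
#'
#' @param path path to the descriptor TSV.
#' @return A numeric matrix with protein ids as rownames.
#' @export
read_gist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  if (length(unique(lengths(vals))) > 1L) {
    stop("descriptor rows have inconsistent lengths")
  }
  out <- do.call(rbind, vals)
  rownames(out) <- ids
  out
}
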