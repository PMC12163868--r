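#' Hyperspectral image cube
#'
#' Container for a single hyperspectral image: a `rows x cols x channels`
#' intensity array together with its spectral axis, spatial calibration and a
#' modality label. All maps and indices in the package are row-major with the
#' origin at the top-left pixel.
#'
#' @param data Numeric 3-D array, `rows x cols x channels`.
#' @param spectral_axis Numeric vector of channel coordinates, strictly
#'   monotonic, length equal to `dim(data)[3]`.
#' @param axis_unit Unit of the spectral axis, `"nm"` (emission wavelength)
#'   or `"cm-1"` (Raman shift).
#' @param pixel_size Square pixel edge length in micrometres (> 0).
#' @param modality Label string, e.g. `"fluorescence"` or `"raman"`.
#'
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(data, spectral_axis, axis_unit = c("nm", "cm-1"),
                     pixel_size = 1, modality = "unknown") {
  axis_unit <- match.arg(axis_unit)
  if (length(dim(data)) != 3L)
    stop("`data` must have exactly 3 axes (rows, cols, channels)")
  spectral_axis <- as.numeric(spectral_axis)
  if (length(spectral_axis) != dim(data)[3L])
    stop("spectral_axis length (", length(spectral_axis),
         ") must equal the channel count (", dim(data)[3L], ")")
  d <- diff(spectral_axis)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("spectral_axis must be strictly monotonic")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(list(data = data, spectral_axis = spectral_axis,
                 axis_unit = axis_unit, pixel_size = pixel_size,
                 modality = as.character(modality)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d px, %d channels [%s %g..%g], %.3g um/px, modality '%s'\n",
              d[1], d[2], d[3], x$axis_unit, min(x$spectral_axis),
              max(x$spectral_axis), x$pixel_size, x$modality))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' Unfold an image cube into a pixels-by-channels matrix
#'
#' The bilinear analysis operates on the unfolded matrix `D` whose rows are
#' pixel spectra. Pixels are taken in row-major order: row 0 col 0 first, then
#' along the first image row. Columns follow the spectral axis.
#'
#' @param cube An [hsi_cube].
#' @return Numeric matrix, `(rows*cols) x channels`.
#' @seealso [refold()]
#' @export
unfold <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  # aperm so that the fastest-varying pixel index is the column (row-major)
  m <- matrix(aperm(cube$data, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
  m
}

#' Refold a pixels-by-channels matrix back into image shape
#'
#' Inverse of [unfold()]: turns rows of a matrix (pixel spectra or
#' concentration profiles in row-major order) back into a
#' `rows x cols x channels` array, e.g. to render distribution maps.
#'
#' @param m Numeric matrix with `rows*cols` rows (a vector is treated as a
#'   one-column matrix).
#' @param shape Integer vector `c(rows, cols)`.
#' @return Array `rows x cols x ncol(m)`.
#' @export
refold <- function(m, shape) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers (rows, cols)")
  if (nrow(m) != prod(shape))
    stop("matrix has ", nrow(m), " rows but shape implies ", prod(shape))
  aperm(array(m, dim = c(shape[2L], shape[1L], ncol(m))), c(2L, 1L, 3L))
}

#' Augmented multiset matrix with explicit missing blocks
#'
#' A multiset is a single 2-D matrix `D` built by concatenating unfolded
#' images row-wise (shared channels) and column-wise (shared pixels). When
#' scanned areas or pixel sizes differ between modalities, some
#' (row block, column block) cells were never measured; these are marked by
#' `observed_mask` rather than imputed. Missingness is block-wise: within one
#' (row block, column block) cell the mask is constant.
#'
#' @param values Numeric matrix, total pixels x total channels. Entries under
#'   an unobserved cell are ignored (stored as 0).
#' @param row_blocks List of row-block descriptors: each a list with `id`,
#'   `rows` (integer index range into `values`), `source` (image id),
#'   `shape` (c(rows, cols) for refolding) and optionally `modalities`.
#' @param col_blocks List of column-block descriptors: each a list with `id`,
#'   `cols` (integer index range), `modality`, `spectral_axis`, `axis_unit`.
#' @param observed Logical matrix `length(row_blocks) x length(col_blocks)`
#'   (the block presence table), or a full logical mask the size of `values`.
#'   Default: everything observed.
#' @return An object of class `multiset_matrix` with elements `values`,
#'   `observed_mask` (full logical matrix), `row_blocks`, `col_blocks`,
#'   `presence` (block-level table).
#' @export
multiset_matrix <- function(values, row_blocks, col_blocks, observed = NULL) {
  values <- as.matrix(values)
  rb <- .check_blocks(row_blocks, nrow(values), "row")
  cb <- .check_blocks(col_blocks, ncol(values), "column")
  K <- length(rb); L <- length(cb)
  if (is.null(observed)) observed <- matrix(TRUE, K, L)
  if (is.logical(observed) && all(dim(observed) == dim(values)) && !(K == nrow(observed) && L == ncol(observed))) {
    presence <- matrix(NA, K, L)
    for (k in seq_len(K)) for (l in seq_len(L)) {
      cell <- observed[rb[[k]]$rows, cb[[l]]$cols]
      u <- unique(as.vector(cell))
      if (length(u) != 1L)
        stop("mask is not constant within block cell (", rb[[k]]$id, ", ", cb[[l]]$id, ")")
      presence[k, l] <- u
    }
  } else {
    presence <- matrix(as.logical(observed), K, L)
  }
  if (anyNA(presence)) stop("presence table contains NA")
  if (any(!apply(presence, 1L, any)))
    stop("layout has a fully missing row block")
  if (any(!apply(presence, 2L, any)))
    stop("layout has a fully missing column block")
  mask <- matrix(FALSE, nrow(values), ncol(values))
  for (k in seq_len(K)) for (l in seq_len(L))
    if (presence[k, l]) mask[rb[[k]]$rows, cb[[l]]$cols] <- TRUE
  values[!mask] <- 0
  structure(list(values = values, observed_mask = mask,
                 row_blocks = rb, col_blocks = cb, presence = presence),
            class = "multiset_matrix")
}

.check_blocks <- function(blocks, n, what) {
  if (!length(blocks)) stop("at least one ", what, " block is required")
  covered <- sort(unlist(lapply(blocks, function(b) {
    r <- b$rows %||% b$cols
    if (is.null(r)) stop(what, " block lacks an index range")
    r
  })))
  if (!identical(covered, seq_len(n)))
    stop(what, " block ranges must partition 1..", n, " with no overlap")
  lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (is.null(b$id)) b$id <- paste0(substr(what, 1, 1), i)
    b
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.multiset_matrix <- function(x, ...) {
  cat(sprintf("<multiset_matrix> %d x %d (%d row blocks x %d col blocks), %.1f%% observed\n",
              nrow(x$values), ncol(x$values), length(x$row_blocks),
              length(x$col_blocks), 100 * mean(x$observed_mask)))
  invisible(x)
}

#' @export
dim.multiset_matrix <- function(x) dim(x$values)

#' Lack of fit and explained variance of a bilinear model
#'
#' Fit quality is summarised by the lack of fit,
#' `LOF = 100 * sqrt(sum(e^2) / sum(d^2))`, and the explained variance,
#' `var = 100 * (1 - sum(e^2) / sum(d^2))`, where the sums run over the
#' observed entries only. Missing entries never enter either sum.
#'
#' @param D Numeric matrix of data values, or a [multiset_matrix].
#' @param E Numeric matrix of residuals, same shape as the data.
#' @param mask Optional logical matrix, `TRUE` for observed entries. Taken
#'   from `D` when `D` is a [multiset_matrix].
#' @return A list of class `fit_metrics`: `lof_percent`, `variance_percent`,
#'   `ssq_residual`, `ssq_data`.
#' @export
fit_metrics <- function(D, E, mask = NULL) {
  if (inherits(D, "multiset_matrix")) {
    if (is.null(mask)) mask <- D$observed_mask
    D <- D$values
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(D), ncol(D))
  if (!all(dim(D) == dim(E)) || !all(dim(D) == dim(mask)))
    stop("D, E and mask must have identical dimensions")
  ssd <- sum(D[mask]^2)
  sse <- sum(E[mask]^2)
  if (ssd == 0) stop("degenerate data: sum of squared observed entries is zero")
  structure(list(lof_percent = 100 * sqrt(sse / ssd),
                 variance_percent = 100 * (1 - sse / ssd),
                 ssq_residual = sse, ssq_data = ssd),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("LOF %.3f %% | explained variance %.3f %%\n",
              x$lof_percent, x$variance_percent))
  invisible(x)
}

#' MCR model container
#'
#' Result of an alternating-least-squares factorization `D = C %*% t(S) + E`:
#' concentration profiles `C` (pixels x components), spectral signatures
#' `S_t` (components x channels), residuals on the observed entries, fit
#' metrics and convergence history. Constructed by [run_mcr_als()] and
#' [run_incomplete_mcr()].
#'
#' @param C Concentration matrix.
#' @param S_t Spectral matrix (components in rows).
#' @param E Residual matrix.
#' @param metrics Overall [fit_metrics].
#' @param history Data frame of per-iteration metrics.
#' @param converged Logical.
#' @param reason Convergence reason string.
#' @param block_metrics Optional per-row-block fit metrics.
#' @param undetermined Optional logical matrix (row blocks x components)
#'   flagging concentrations not determined by any observed signal.
#' @return Object of class `mcr_model`.
#' @export
mcr_model <- function(C, S_t, E, metrics, history, converged, reason,
                      block_metrics = NULL, undetermined = NULL) {
  stopifnot(nrow(S_t) == ncol(C), all(dim(E) == c(nrow(C), ncol(S_t))))
  structure(list(C = C, S_t = S_t, E = E, n_components = ncol(C),
                 metrics = metrics, history = history, converged = converged,
                 reason = reason, block_metrics = block_metrics,
                 undetermined = undetermined),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf("<mcr_model> %d components, %d pixels x %d channels\n",
              x$n_components, nrow(x$C), ncol(x$S_t)))
  cat(sprintf("  %s after %d iterations (%s)\n",
              if (x$converged) "converged" else "stopped", nrow(x$history), x$reason))
  print(x$metrics)
  invisible(x)
}
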