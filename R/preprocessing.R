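#' Preprocessing configuration
#'
#' Bundles the parameters of the spectral/spatial preprocessing chain applied
#' to Raman and fluorescence cubes before unmixing.
#'
#' @param bin_factor Spatial binning factor (adjacent pixel spectra are
#'   summed in `bin_factor x bin_factor` blocks).
#' @param spike_mad_threshold Robust z-score above which a channel is flagged
#'   as a cosmic spike.
#' @param spike_window Odd running-median window length for spike detection.
#' @param svd_rank Rank kept by the SVD-Fourier denoiser.
#' @param fourier_cutoff Low-pass cutoff as a fraction of the Nyquist
#'   frequency, in (0, 1]; 1 disables the Fourier step.
#' @param asls_lambda Smoothness penalty of the asymmetric least squares
#'   baseline.
#' @param asls_p Asymmetry weight in (0, 1); small values hug the lower
#'   envelope.
#' @param asls_iters Number of reweighting iterations.
#' @param range_lo,range_hi Spectral range kept for analysis (inclusive), in
#'   axis units.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(bin_factor = 2L, spike_mad_threshold = 8,
                              spike_window = 7L, svd_rank = 10L,
                              fourier_cutoff = 0.5, asls_lambda = 1e5,
                              asls_p = 0.001, asls_iters = 10L,
                              range_lo = 640, range_hi = 1750) {
  stopifnot(bin_factor >= 1, spike_mad_threshold > 0,
            spike_window >= 3, spike_window %% 2 == 1,
            svd_rank >= 1, fourier_cutoff > 0, fourier_cutoff <= 1,
            asls_lambda > 0, asls_p > 0, asls_p < 1, asls_iters >= 1)
  structure(list(bin_factor = as.integer(bin_factor),
                 spike_mad_threshold = spike_mad_threshold,
                 spike_window = as.integer(spike_window),
                 svd_rank = as.integer(svd_rank),
                 fourier_cutoff = fourier_cutoff,
                 asls_lambda = asls_lambda, asls_p = asls_p,
                 asls_iters = as.integer(asls_iters),
                 range_lo = range_lo, range_hi = range_hi),
            class = "preprocess_config")
}

#' Spatial binning of an image cube
#'
#' Sums the spectra of adjacent pixels in `factor x factor` blocks, producing
#' one larger pixel per block. Total intensity is conserved on divisible
#' grids; trailing rows/columns that do not fill a whole block are dropped.
#' The pixel size is multiplied by `factor`.
#'
#' @param cube An [hsi_cube].
#' @param factor Positive integer binning factor; 1 returns the input.
#' @return Binned [hsi_cube].
#' @export
bin_spatial <- function(cube, factor) {
  stopifnot(inherits(cube, "hsi_cube"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("binning factor must be >= 1")
  if (factor == 1L) return(cube)
  d <- dim(cube$data)
  nr <- d[1L] %/% factor
  nc <- d[2L] %/% factor
  if (nr < 1L || nc < 1L) stop("cube smaller than one binning block")
  x <- cube$data[seq_len(nr * factor), seq_len(nc * factor), , drop = FALSE]
  # collapse each factor x factor block by summation, per channel
  x <- array(x, dim = c(factor, nr, factor * nc * d[3L]))
  x <- colSums(x)                                  # nr x (factor*nc*chan)
  x <- array(x, dim = c(nr, factor, nc * d[3L]))
  x <- aperm(x, c(2L, 1L, 3L))
  x <- colSums(x)                                  # nr x (nc*chan)
  out <- array(x, dim = c(nr, nc, d[3L]))
  hsi_cube(out, cube$spectral_axis, cube$axis_unit,
           pixel_size = cube$pixel_size * factor, modality = cube$modality)
}

#' Cosmic spike removal from a single spectrum
#'
#' Channels whose deviation from a running median exceeds
#' `spike_mad_threshold` times the median absolute deviation of those
#' deviations are flagged as cosmic spikes and replaced by linear
#' interpolation between the nearest unflagged neighbours; flagged channels
#' at either end take the nearest unflagged value.
#'
#' @param spectrum Numeric vector of intensities.
#' @param config A [preprocess_config] (uses `spike_window` and
#'   `spike_mad_threshold`).
#' @return List with `spectrum` (cleaned) and `spikes` (integer indices of
#'   replaced channels).
#' @export
remove_cosmic_spikes <- function(spectrum, config = preprocess_config()) {
  y <- as.numeric(spectrum)
  n <- length(y)
  if (n < 3L) stop("spectrum must have at least 3 channels")
  w <- min(config$spike_window, n - 1L + n %% 2L)  # largest odd window <= n
  med <- stats::runmed(y, w, endrule = "median")
  dev <- y - med
  # the running median passes exactly through the centre sample on locally
  # monotone stretches, so a large share of the deviations is exactly zero;
  # the robust scale must come from the nonzero deviations
  s <- stats::mad(dev)
  if (s == 0 && any(dev != 0)) s <- stats::mad(dev[dev != 0])
  if (s > 0) {
    flag <- abs(dev) > config$spike_mad_threshold * s
  } else {
    # noiseless/piecewise-constant case: any non-trivial departure from the
    # running median is a spike
    flag <- abs(dev) > 1e-8 * max(abs(y), 1e-300)
  }
  if (all(flag)) stop("degenerate spectrum: every channel flagged as a spike")
  if (any(flag)) {
    keep <- which(!flag)
    y[flag] <- stats::approx(keep, y[keep], xout = which(flag),
                             rule = 2)$y
  }
  list(spectrum = y, spikes = which(flag))
}

#' Despike every pixel of a cube
#'
#' Applies [remove_cosmic_spikes()] to each pixel spectrum.
#'
#' @inheritParams remove_cosmic_spikes
#' @param cube An [hsi_cube].
#' @return List with `cube` (cleaned) and `n_spikes` (total spikes replaced).
#' @export
despike_cube <- function(cube, config = preprocess_config()) {
  m <- unfold(cube)
  total <- 0L
  for (i in seq_len(nrow(m))) {
    r <- remove_cosmic_spikes(m[i, ], config)
    m[i, ] <- r$spectrum
    total <- total + length(r$spikes)
  }
  list(cube = hsi_cube(refold(m, dim(cube$data)[1:2]), cube$spectral_axis,
                       cube$axis_unit, cube$pixel_size, cube$modality),
       n_spikes = total)
}

#' SVD plus Fourier low-pass denoising
#'
#' The unfolded image is approximated by its rank-`rank` truncated singular
#' value decomposition; each retained right singular vector (a spectral
#' direction) is additionally low-pass filtered by zeroing Fourier
#' coefficients above `cutoff` times the Nyquist frequency before
#' reconstruction. `cutoff = 1` disables the Fourier step, reducing the
#' operation to plain truncated SVD.
#'
#' @param m Numeric matrix (pixels x channels).
#' @param rank Number of singular components kept, `1 <= rank <= min(dim(m))`.
#' @param cutoff Fraction of the Nyquist frequency retained, in (0, 1].
#' @return Denoised matrix of the same shape.
#' @export
svd_fourier_denoise <- function(m, rank, cutoff = 0.5) {
  m <- as.matrix(m)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(m))) stop("rank out of range 1..min(dim)")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  sv <- svd(m, nu = rank, nv = rank)
  V <- sv$v
  if (cutoff < 1) {
    n <- nrow(V)
    f <- pmin(0:(n - 1), n - (0:(n - 1)))     # two-sided frequency index
    keep <- f <= cutoff * (n / 2)
    V <- apply(V, 2L, function(v) Re(stats::fft(stats::fft(v) * keep,
                                                inverse = TRUE)) / n)
    V <- matrix(V, nrow = n)
  }
  sv$u %*% (sv$d[seq_len(rank)] * t(V))
}

#' Asymmetric least squares baseline
#'
#' Estimates a smooth baseline `z` minimizing
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` with
#' asymmetric weights `w = p` where `y > z` and `1 - p` otherwise, iterated a
#' fixed number of times. With small `p` the baseline hugs the lower envelope
#' beneath the peaks.
#'
#' @param spectrum Numeric vector (length >= 3).
#' @param lambda Smoothness penalty (> 0).
#' @param p Asymmetry in (0, 1).
#' @param iters Reweighting iterations.
#' @return Numeric baseline vector the same length as `spectrum`; subtract it
#'   from the spectrum to correct the background.
#' @export
asls_baseline <- function(spectrum, lambda = 1e5, p = 0.001, iters = 10L) {
  y <- as.numeric(spectrum)
  n <- length(y)
  if (n < 3L) stop("spectrum must have at least 3 channels")
  if (lambda <= 0) stop("lambda must be positive")
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D2)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Restrict a cube to a spectral range
#'
#' Keeps only the channels whose spectral-axis value lies in
#' `[lo, hi]` (inclusive on both ends), subsetting the axis accordingly.
#'
#' @param cube An [hsi_cube].
#' @param lo,hi Range bounds in axis units, `lo < hi`.
#' @return Cropped [hsi_cube].
#' @export
select_spectral_range <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (lo >= hi) stop("range bounds must satisfy lo < hi")
  keep <- cube$spectral_axis >= lo & cube$spectral_axis <= hi
  if (!any(keep)) stop("selected range contains no spectral channels")
  hsi_cube(cube$data[, , keep, drop = FALSE], cube$spectral_axis[keep],
           cube$axis_unit, cube$pixel_size, cube$modality)
}

#' Full Raman preprocessing chain
#'
#' Convenience wrapper applying, in order: cosmic-spike removal per pixel,
#' SVD-Fourier denoising, asymmetric least squares baseline subtraction per
#' pixel, and spectral range selection, with parameters from a
#' [preprocess_config]. Spatial binning is left to the caller because the
#' binning factor depends on the target grid (see [bin_spatial()]).
#'
#' @param cube Raman [hsi_cube].
#' @param config A [preprocess_config].
#' @return List with `cube` (preprocessed) and `n_spikes`.
#' @export
preprocess_raman <- function(cube, config = preprocess_config()) {
  ds <- despike_cube(cube, config)
  m <- unfold(ds$cube)
  rk <- min(config$svd_rank, dim(m))
  m <- svd_fourier_denoise(m, rk, config$fourier_cutoff)
  for (i in seq_len(nrow(m)))
    m[i, ] <- m[i, ] - asls_baseline(m[i, ], config$asls_lambda,
                                     config$asls_p, config$asls_iters)
  out <- hsi_cube(refold(m, dim(cube$data)[1:2]), cube$spectral_axis,
                  cube$axis_unit, cube$pixel_size, cube$modality)
  list(cube = select_spectral_range(out, config$range_lo, config$range_hi),
       n_spikes = ds$n_spikes)
}
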