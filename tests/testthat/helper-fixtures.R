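# small in-code fixtures shared across test files

random_cube <- function(rows, cols, chan, seed = 1, unit = "nm") {
  set.seed(seed)
  hsi_cube(array(runif(rows * cols * chan), c(rows, cols, chan)),
           seq_len(chan), unit, pixel_size = 0.2, modality = "test")
}

# smooth spot-pattern map (widely spaced Gaussian blobs), used as a
# registration phantom
spot_map <- function(n = 48, k = 10, width = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  rg <- row(m); cg <- col(m)
  for (i in seq_len(k)) {
    r <- runif(1, 10, n - 10); c <- runif(1, 10, n - 10)
    m <- m + exp(-((rg - r)^2 + (cg - c)^2) / width)
  }
  m
}

# exact dense least squares on an explicit sub-system, independent of the
# package's solvers (QR, not normal equations)
ls_oracle <- function(A, b) qr.solve(A, b)

# exhaustive-support non-negative least squares oracle for small p
nnls_oracle <- function(A, b) {
  p <- ncol(A)
  best <- rep(0, p); bv <- sum(b^2)
  for (s in seq_len(2^p) - 1L) {
    idx <- as.logical(bitwAnd(s, 2^(seq_len(p) - 1L)))
    x <- rep(0, p)
    if (any(idx)) {
      xi <- tryCatch(qr.solve(A[, idx, drop = FALSE], b),
                     error = function(e) NULL)
      if (is.null(xi) || any(xi < -1e-12)) next
      x[idx] <- xi
    }
    v <- sum((A %*% x - b)^2)
    if (v < bv - 1e-12) { bv <- v; best <- x }
  }
  best
}

# a small fully observed one-block multiset around a matrix
as_multiset <- function(D) {
  multiset_matrix(D, list(list(id = "r1", rows = seq_len(nrow(D)))),
                  list(list(id = "c1", cols = seq_len(ncol(D)))))
}

# unfold a map stack into a concentration matrix (row-major pixel order)
maps_to_C <- function(maps) {
  unfold(hsi_cube(maps, seq_len(dim(maps)[3]), "nm", 1, "maps"))
}

# 3-component noiseless phantom image for complete-data MCR tests
simple_bilinear <- function(seed = 4, npix = 150, nchan = 40, n = 3) {
  set.seed(seed)
  S <- matrix(0, n, nchan)
  for (k in seq_len(n))
    S[k, ] <- exp(-((seq_len(nchan) - (7 + 12 * k)) / 4)^2) +
      0.3 * exp(-((seq_len(nchan) - 20) / 10)^2)
  C <- matrix(runif(npix * n)^2, npix)
  C[seq_len(n), ] <- diag(n) * 2     # plant pure pixels
  list(C = C, S_t = S, D = C %*% S)
}
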