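test_that("spatial binning sums blocks, conserves intensity, scales pixels", {
  ones <- hsi_cube(array(1, c(4, 4, 1)), 1, "nm", 0.2, "f")
  b2 <- bin_spatial(ones, 2)
  expect_equal(b2$data[, , 1], matrix(4, 2, 2))
  expect_equal(sum(b2$data), sum(ones$data))
  expect_equal(bin_spatial(ones, 4)$pixel_size, 0.8)

  cube <- random_cube(8, 6, 5, seed = 2)
  expect_identical(bin_spatial(cube, 1), cube)
  b <- bin_spatial(cube, 2)
  expect_equal(sum(b$data), sum(cube$data))
  expect_equal(b$data[1, 1, ], colSums(unfold(cube)[c(1, 2, 7, 8), ]))

  # trailing pixels that do not fill a block are dropped
  odd <- random_cube(5, 5, 2, seed = 3)
  expect_equal(dim(bin_spatial(odd, 2))[1:2], c(2, 2))
  expect_error(bin_spatial(cube, 0), ">= 1")
})

test_that("cosmic spikes are flagged and replaced by interpolation", {
  r <- remove_cosmic_spikes(c(1, 1, 50, 1, 1))
  expect_equal(r$spikes, 3)
  expect_equal(r$spectrum, rep(1, 5))

  flat <- remove_cosmic_spikes(rep(2, 20))
  expect_length(flat$spikes, 0)
  expect_equal(flat$spectrum, rep(2, 20))

  edge <- remove_cosmic_spikes(c(50, rep(1, 9)))
  expect_equal(edge$spikes, 1)
  expect_equal(edge$spectrum[1], 1)   # terminal spike takes nearest value

  expect_error(remove_cosmic_spikes(c(1, 2)), "at least 3")
})

test_that("despiking is idempotent and restores planted spikes", {
  set.seed(14)
  x <- seq(640, 1750, 2)
  for (t in 1:10) {
    clean <- 2 + sin(x / 90) + 0.8 * exp(-((x - 1200) / 40)^2)
    y <- clean + rnorm(length(x), 0, 0.01)
    idx <- sample(length(x), 4)
    y[idx] <- y[idx] + runif(4, 3, 10)
    r1 <- remove_cosmic_spikes(y)
    expect_true(all(idx %in% r1$spikes))
    r2 <- remove_cosmic_spikes(r1$spectrum)
    expect_length(r2$spikes, 0)
    rms <- sqrt(mean((r1$spectrum - clean)^2)) / sqrt(mean(clean^2))
    expect_lt(rms, 0.01)
  }
})

test_that("SVD-Fourier denoiser reduces to truncated SVD at cutoff 1", {
  set.seed(5)
  # exactly rank-2 input is reproduced
  A <- outer(rnorm(20), rnorm(15)) + outer(rnorm(20), rnorm(15))
  expect_lt(norm(svd_fourier_denoise(A, 2, 1) - A, "F") / norm(A, "F"), 1e-9)

  M <- matrix(rnorm(30 * 12), 30)
  expect_equal(svd_fourier_denoise(M, 12, 1), M, tolerance = 1e-9)

  for (t in 1:5) {
    M <- matrix(rnorm(25 * 18), 25)
    k <- sample(1:6, 1)
    sv <- svd(M)
    plain <- sv$u[, 1:k, drop = FALSE] %*%
      (sv$d[1:k] * t(sv$v[, 1:k, drop = FALSE]))
    expect_equal(svd_fourier_denoise(M, k, 1), plain, tolerance = 1e-9)
  }
  expect_error(svd_fourier_denoise(M, 0, 1), "rank")
})

test_that("SVD-Fourier beats plain truncation on a smooth noisy signal", {
  set.seed(8)
  u <- sin(seq(0, 3 * pi, length.out = 50))
  v <- exp(-((1:80 - 40) / 15)^2)
  clean <- outer(u, v)
  noisy <- clean + matrix(rnorm(50 * 80, 0, 0.05), 50)
  sv <- svd(noisy)
  plain <- sv$d[1] * outer(sv$u[, 1], sv$v[, 1])
  den <- svd_fourier_denoise(noisy, 1, 0.5)
  expect_lte(norm(den - clean, "F"), norm(plain - clean, "F"))
})

test_that("AsLS baseline tracks smooth peak-free inputs", {
  expect_equal(asls_baseline(rep(0, 50)), rep(0, 50), tolerance = 1e-9)

  y <- seq(1, 5, length.out = 120)
  bl <- asls_baseline(y)
  expect_lt(sqrt(mean((bl - y)^2)) / sqrt(mean(y^2)), 0.01)

  # line + single Gaussian peak: corrected peak area within 5 %
  x <- 1:200
  peak <- 5 * exp(-((x - 100) / 8)^2)
  y2 <- (2 + 0.01 * x) + peak
  corrected <- y2 - asls_baseline(y2)
  expect_equal(sum(corrected) / sum(peak), 1, tolerance = 0.05)

  expect_error(asls_baseline(c(1, 2)), "at least 3")
  expect_error(asls_baseline(1:10, lambda = -1), "positive")
})

test_that("AsLS baseline is equivariant to adding a constant", {
  set.seed(9)
  y <- 3 + cumsum(rnorm(100, 0, 0.05)) + 2 * exp(-((1:100 - 60) / 5)^2)
  expect_equal(asls_baseline(y + 7), asls_baseline(y) + 7, tolerance = 1e-6)
})

test_that("spectral range selection is inclusive on both bounds", {
  cube <- hsi_cube(array(runif(601), c(1, 1, 601)), seq(600, 1800, 2),
                   "cm-1", 0.2, "raman")
  sel <- select_spectral_range(cube, 640, 1750)
  expect_equal(dim(sel)[3], 556)
  expect_equal(range(sel$spectral_axis), c(640, 1750))

  full <- select_spectral_range(cube, 600, 1800)
  expect_identical(full$data, cube$data)
  expect_error(select_spectral_range(cube, 1750, 640), "lo < hi")
  expect_error(select_spectral_range(cube, 5000, 6000), "no spectral")
})

test_that("the Raman chain despikes, denoises and flattens the baseline", {
  spec <- phantom_spec(seed = 21, noise_sd = 0.01, baseline_amplitude = 0.2,
                       spike_rate = 2e-4)
  S_r <- generate_pure_spectra(spec, "raman")
  maps <- generate_phantom_maps(spec)[33:40, 33:40, , drop = FALSE]
  cube <- simulate_measurement(maps, S_r, spec, "raman")
  expect_gt(attr(cube, "n_spikes"), 0)
  res <- preprocess_raman(cube, preprocess_config(svd_rank = 8))
  clean <- maps_to_C(maps) %*% S_r
  err_raw <- norm(unfold(cube) - clean, "F")
  err_pp <- norm(unfold(res$cube) - clean, "F")
  expect_lt(err_pp, 0.35 * err_raw)
  expect_gt(res$n_spikes, 0)
})
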