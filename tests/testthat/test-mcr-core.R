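test_that("multi-column NNLS agrees with the exhaustive-support oracle", {
  set.seed(40)
  for (t in 1:30) {
    p <- sample(2:5, 1)
    A <- matrix(rnorm(10 * p), 10)
    B <- matrix(rnorm(10 * 4), 10)
    X <- nnls_multi(crossprod(A), crossprod(A, B))
    expect_true(all(X >= 0))
    for (j in 1:4)
      expect_equal(X[, j], nnls_oracle(A, B[, j]), tolerance = 1e-6)
  }
})

test_that("least-squares half-steps reproduce exact bilinear data", {
  set.seed(41)
  Ct <- matrix(runif(20 * 3), 20); St <- matrix(runif(3 * 15), 3)
  D <- Ct %*% St
  expect_equal(update_C(D, St), Ct, tolerance = 1e-9)
  expect_equal(update_S(D, Ct), St, tolerance = 1e-9)

  # orthonormal spectra collapse the normal equations to a projection
  Q <- qr.Q(qr(matrix(rnorm(15 * 3), 15)))
  expect_equal(update_C(D, t(Q)), D %*% Q, tolerance = 1e-9)

  # pure-pixel indicator rows pick out those pixels' spectra
  Cp <- matrix(0, 6, 2); Cp[2, 1] <- 1; Cp[5, 2] <- 1
  D2 <- Cp %*% St[1:2, ]
  expect_equal(update_S(D2, Cp), St[1:2, ], tolerance = 1e-9)

  # random small case against an independent QR solve
  D3 <- matrix(rnorm(6 * 4), 6); S3 <- matrix(rnorm(3 * 4), 3)
  C3 <- update_C(D3, S3)
  for (i in 1:6)
    expect_equal(C3[i, ], ls_oracle(t(S3), D3[i, ]), tolerance = 1e-9)

  # collinear spectra are rejected with a named diagnostic
  Sc <- rbind(St[1, ], St[1, ] * 2, St[3, ])
  expect_error(update_C(D, Sc), "collinear")
})

test_that("SIMPLISMA picks pure pixels and is deterministic", {
  set.seed(42)
  S <- rbind(c(1, 0, 0, 0.2, 0.1), c(0, 1, 0.3, 0, 0.2))
  C <- matrix(runif(40 * 2), 40)
  C[7, ] <- c(1, 0); C[23, ] <- c(0, 1)      # two pure pixels
  D <- C %*% S
  S0 <- simplisma_initial_spectra(D, 2)
  Sn <- S / sqrt(rowSums(S^2))
  cos_best <- apply(abs(S0 %*% t(Sn)), 1, max)
  expect_true(all(cos_best >= 0.999))
  expect_equal(sqrt(rowSums(S0^2)), c(1, 1))

  expect_identical(simplisma_initial_spectra(D, 2),
                   simplisma_initial_spectra(D, 2))

  # n = 1 maximizes the plain purity ratio (brute-force oracle)
  mu <- rowMeans(D); sg <- sqrt(rowMeans(D^2) - mu^2)
  off <- 0.05 * max(mu)
  expect_equal(attr(simplisma_initial_spectra(D, 1), "rows"),
               which.max(sg / (mu + off)))
})

test_that("constraint application clips, re-solves and zeroes exactly", {
  cs_clip <- constraint_set(nonneg_mode = "clip")
  expect_equal(apply_constraints(rbind(c(-1, 2)), cs_clip, "C"),
               rbind(c(0, 2)))

  # 2-variable NNLS re-solve against the exhaustive oracle
  set.seed(43)
  A <- matrix(rnorm(12 * 2), 12); D <- matrix(rnorm(12 * 5), 12)
  cs_nnls <- constraint_set(nonneg_mode = "nnls")
  Sfit <- apply_constraints(matrix(0, 2, 5), cs_nnls, "S", D = D, other = A)
  for (j in 1:5)
    expect_equal(Sfit[, j], nnls_oracle(A, D[, j]), tolerance = 1e-6)

  # equality-to-zero spectral segment
  St <- matrix(runif(12), 2, 6)
  cb <- list(list(id = "fluo", cols = 1:3), list(id = "raman", cols = 4:6))
  cs_z <- constraint_set(zero_S_segments = list(c(2, "fluo")))
  Sz <- apply_constraints(St, cs_z, "S", blocks = cb)
  expect_equal(Sz[2, 1:3], c(0, 0, 0))
  expect_equal(Sz[1, ], St[1, ])
})

test_that("a component zeroed in every column block is rejected", {
  sim <- simple_bilinear()
  cb <- list(list(id = "a", cols = 1:20), list(id = "b", cols = 21:40))
  cs <- constraint_set(zero_S_segments = list(c(1, "a"), c(1, "b")))
  expect_error(run_mcr_als(sim$D, S0 = sim$S_t, constraints = cs,
                           col_blocks = cb),
               "every column block")
})

test_that("ALS recovers a noiseless phantom and satisfies its contracts", {
  sim <- simple_bilinear()
  S0 <- simplisma_initial_spectra(sim$D, 3)
  model <- run_mcr_als(sim$D, S0 = S0, constraints = constraint_set(),
                       convergence = convergence_spec(max_iters = 60))
  mt <- match_components(model$S_t, sim$S_t)
  expect_true(all(mt$cosines >= 0.999))
  mtC <- match_components(t(model$C), t(sim$C))
  expect_true(all(mtC$cosines >= 0.999))

  expect_true(all(model$C >= 0))
  expect_true(all(model$S_t >= 0))
  expect_lte(nrow(model$history), 60)
  expect_true(is.character(model$reason) && nzchar(model$reason))
  # residual contract: E = D - C St at return time
  expect_equal(model$E, sim$D - model$C %*% model$S_t, tolerance = 1e-12)
  # spectra normalized to unit norm
  expect_equal(sqrt(rowSums(model$S_t^2)), rep(1, 3), tolerance = 1e-9)
})

test_that("unconstrained ALS never increases the residual sum of squares", {
  set.seed(44)
  D <- matrix(runif(80 * 25), 80) + 0.05
  S0 <- simplisma_initial_spectra(D, 4)
  cs <- constraint_set(nonneg_C = FALSE, nonneg_S = FALSE)
  model <- run_mcr_als(D, S0 = S0, constraints = cs,
                       convergence = convergence_spec(max_iters = 15,
                                                      lof_change_tol = 0))
  h <- model$history
  seq_ssq <- as.vector(rbind(h$ssq_after_C, h$ssq_after_S))
  expect_true(all(diff(seq_ssq) <= 1e-8 * seq_ssq[1]))
})

test_that("parameter recovery holds across seeds, with and without noise", {
  # fluorescence phantoms: three labeled constituents with structured maps
  ok_clean <- ok_noisy <- numeric(0)
  for (sd in 1:20) {
    spec0 <- phantom_spec(rows = 48, cols = 48, seed = 200 + sd, noise_sd = 0)
    maps <- generate_phantom_maps(spec0)
    Sf <- generate_pure_spectra(spec0, "fluorescence")
    truth <- Sf[spec0$components$fluorescent, ]
    cube0 <- bin_spatial(simulate_measurement(maps, Sf, spec0,
                                              "fluorescence"), 2)
    D0 <- unfold(cube0)
    m <- run_mcr_als(D0, S0 = simplisma_initial_spectra(D0, 3),
                     convergence = convergence_spec(max_iters = 40))
    ok_clean <- c(ok_clean, match_components(m$S_t, truth)$mean_cosine)

    spec5 <- phantom_spec(rows = 48, cols = 48, seed = 200 + sd,
                          noise_sd = 0.05)
    cube5 <- bin_spatial(simulate_measurement(maps, Sf, spec5,
                                              "fluorescence"), 2)
    D5 <- unfold(cube5)
    mn <- run_mcr_als(D5, S0 = simplisma_initial_spectra(D5, 3),
                      convergence = convergence_spec(max_iters = 40))
    ok_noisy <- c(ok_noisy, match_components(mn$S_t, truth)$mean_cosine)
  }
  expect_gte(mean(ok_clean), 0.999)
  expect_gte(mean(ok_noisy), 0.98)
})

test_that("component matching maximizes total cosine over permutations", {
  set.seed(45)
  A <- matrix(runif(4 * 10), 4)
  perm <- c(3, 1, 4, 2)
  B <- A[perm, ] * runif(4, 0.5, 2)   # scale must not matter
  mt <- match_components(A, B)
  expect_equal(mt$perm[perm], 1:4)
  expect_true(all(mt$cosines >= 0.999))
})

test_that("the SVD scree reports cumulative variance", {
  sim <- simple_bilinear()
  sc <- svd_scree(sim$D, 6)
  expect_equal(nrow(sc), 6)
  expect_gt(sc$cumulative_percent[3], 99.9)   # exactly rank 3
  expect_true(all(diff(sc$singular_value) <= 0))
})
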