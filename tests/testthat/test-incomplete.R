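test_that("incomplete multiset assembly lays out blocks and masks", {
  set.seed(50)
  core_f <- matrix(runif(100 * 57), 100)
  core_r <- matrix(runif(100 * 556), 100)
  fused <- fuse_rowwise(list(fluorescence = core_f, raman = core_r))
  extra_f <- list(values = matrix(runif(400 * 57), 400),
                  modality = "fluorescence", id = "cell1")
  extra_r <- list(values = matrix(runif(250 * 556), 250),
                  modality = "raman", id = "r4A")
  ms <- assemble_incomplete_multiset(fused, list(extra_f, extra_r))
  expect_equal(dim(ms$values), c(750, 613))
  # fluorescence-only rows on top, core in the middle, Raman at the bottom
  expect_equal(vapply(ms$row_blocks, function(b) b$id, ""),
               c("cell1", "core", "r4A"))
  expect_false(any(ms$observed_mask[1:400, 58:613]))
  expect_false(any(ms$observed_mask[501:750, 1:57]))
  expect_true(all(ms$observed_mask[401:500, ]))
  expect_identical(ms$values[401:500, 1:57], core_f)

  ms0 <- assemble_incomplete_multiset(fused)
  expect_true(all(ms0$observed_mask))
  expect_identical(ms0$values, fused$values)

  bad <- list(values = matrix(0, 10, 58), modality = "fluorescence")
  expect_error(assemble_incomplete_multiset(fused, list(bad)), "channels")
})

test_that("masked updates reduce to the dense updates on full observation", {
  set.seed(51)
  D <- matrix(rnorm(30 * 12), 30)
  ms <- as_multiset(D)
  St <- matrix(rnorm(4 * 12), 4)
  C <- matrix(rnorm(30 * 4), 30)
  expect_equal(unclass(update_C_missing(ms, St)), update_C(D, St),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(update_S_missing(ms, C), update_S(D, C), tolerance = 1e-12)
})

test_that("masked updates equal dense least squares on the observed parts", {
  set.seed(52)
  rb <- list(list(id = "a", rows = 1:5), list(id = "b", rows = 6:9),
             list(id = "c", rows = 10:14))
  cb <- list(list(id = "x", cols = 1:6), list(id = "y", cols = 7:11))
  for (t in 1:40) {
    pres <- matrix(runif(6) > 0.3, 3, 2)
    for (k in 1:3) if (!any(pres[k, ])) pres[k, sample(2, 1)] <- TRUE
    for (l in 1:2) if (!any(pres[, l])) pres[sample(3, 1), l] <- TRUE
    ms <- multiset_matrix(matrix(rnorm(14 * 11), 14), rb, cb, observed = pres)
    St <- matrix(rnorm(3 * 11), 3)
    C <- update_C_missing(ms, St)
    for (k in 1:3) {
      obs <- unlist(lapply(which(pres[k, ]), function(l) cb[[l]]$cols))
      for (i in rb[[k]]$rows)
        expect_equal(C[i, ], ls_oracle(t(St[, obs, drop = FALSE]),
                                       ms$values[i, obs]),
                     ignore_attr = TRUE, tolerance = 1e-9)
    }
    Cm <- matrix(rnorm(14 * 3), 14)
    St2 <- update_S_missing(ms, Cm)
    for (l in 1:2) {
      obs <- unlist(lapply(which(pres[, l]), function(k) rb[[k]]$rows))
      for (j in cb[[l]]$cols)
        expect_equal(St2[, j], ls_oracle(Cm[obs, , drop = FALSE],
                                         ms$values[obs, j]),
                     tolerance = 1e-9)
    }
  }
})

test_that("components without observed signal in a block are flagged", {
  # two column blocks; component 3 is zero over the observed block of row
  # block "top", so its coefficients there are undetermined
  set.seed(53)
  rb <- list(list(id = "top", rows = 1:6), list(id = "core", rows = 7:12))
  cb <- list(list(id = "fluo", cols = 1:5), list(id = "raman", cols = 6:12))
  St <- matrix(runif(3 * 12), 3)
  St[3, 1:5] <- 0
  Ct <- matrix(runif(12 * 3), 12)
  V <- Ct %*% St
  pres <- rbind(c(TRUE, FALSE), c(TRUE, TRUE))
  ms <- multiset_matrix(V, rb, cb, observed = pres)
  C <- update_C_missing(ms, St)
  und <- attr(C, "undetermined")
  expect_true(und["top", 3])
  expect_false(any(und["core", ]))
  expect_equal(C[1:6, 3], rep(0, 6))
  # identifiable components are still recovered exactly in that block
  expect_equal(C[7:12, ], Ct[7:12, ], tolerance = 1e-9)
})

test_that("with no missing blocks the incomplete driver equals the complete one", {
  set.seed(54)
  Ct <- matrix(runif(60 * 3), 60)
  St <- matrix(runif(3 * 20), 3)
  D <- Ct %*% St + matrix(rnorm(60 * 20, 0, 0.01), 60)
  ms <- as_multiset(D)
  S0 <- simplisma_initial_spectra(D, 3)
  conv <- convergence_spec(max_iters = 10, lof_change_tol = 0)
  for (cs in list(constraint_set(nonneg_C = FALSE, nonneg_S = FALSE),
                  constraint_set())) {
    m1 <- run_mcr_als(D, S0 = S0, constraints = cs, convergence = conv)
    m2 <- run_incomplete_mcr(ms, S0, cs, conv)
    expect_lt(max(abs(m1$C - m2$C)), 1e-10)
    expect_lt(max(abs(m1$S_t - m2$S_t)), 1e-10)
    expect_equal(m1$history$lof_percent, m2$history$lof_percent,
                 tolerance = 1e-12)
  }
})

test_that("incomplete ALS decreases the observed residual monotonically", {
  set.seed(55)
  rb <- list(list(id = "a", rows = 1:20), list(id = "b", rows = 21:50),
             list(id = "c", rows = 51:70))
  cb <- list(list(id = "x", cols = 1:8), list(id = "y", cols = 9:20))
  pres <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, TRUE))
  V <- matrix(runif(70 * 20), 70)
  ms <- multiset_matrix(V, rb, cb, observed = pres)
  core <- which(rowSums(ms$observed_mask) == 20)
  S0 <- simplisma_initial_spectra(ms$values[core, ], 3)
  m <- run_incomplete_mcr(ms, S0,
                          constraint_set(nonneg_C = FALSE, nonneg_S = FALSE),
                          convergence_spec(max_iters = 12, lof_change_tol = 0))
  h <- m$history
  seq_ssq <- as.vector(rbind(h$ssq_after_C, h$ssq_after_S))
  expect_true(all(diff(seq_ssq) <= 1e-8 * seq_ssq[1]))
  # per-block metrics cover every row block
  expect_named(m$block_metrics, c("a", "b", "c"))
})

test_that("equality constraints hold exactly in the returned model", {
  set.seed(56)
  rb <- list(list(id = "top", rows = 1:25), list(id = "core", rows = 26:60))
  cb <- list(list(id = "fluo", cols = 1:10), list(id = "raman", cols = 11:30))
  St <- matrix(runif(3 * 30), 3); St[2, 1:10] <- 0
  Ct <- matrix(runif(60 * 3), 60); Ct[1:25, 3] <- 0
  V <- Ct %*% St
  pres <- rbind(c(TRUE, FALSE), c(TRUE, TRUE))
  ms <- multiset_matrix(V, rb, cb, observed = pres)
  cs <- constraint_set(zero_C_blocks = list(c("top", 3)),
                       zero_S_segments = list(c(2, "fluo")))
  m <- run_incomplete_mcr(ms, St + 0.01 * matrix(runif(90), 3), cs,
                          convergence_spec(max_iters = 30))
  expect_true(all(m$C[1:25, 3] == 0))
  expect_true(all(m$S_t[2, 1:10] == 0))
  expect_true(all(m$C >= 0) && all(m$S_t >= 0))
})

test_that("missing blocks are predicted by the fitted bilinear model", {
  set.seed(57)
  rb <- list(list(id = "top", rows = 1:15), list(id = "core", rows = 16:40),
             list(id = "bot", rows = 41:55))
  cb <- list(list(id = "fluo", cols = 1:8), list(id = "raman", cols = 9:24))
  St <- matrix(runif(3 * 24), 3); St[3, 1:8] <- 0
  Ct <- matrix(runif(55 * 3), 55)
  V_full <- Ct %*% St
  pres <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, TRUE))
  ms <- multiset_matrix(V_full, rb, cb, observed = pres)
  cs <- constraint_set(zero_S_segments = list(c(3, "fluo")))
  m <- run_incomplete_mcr(ms, St, cs, convergence_spec(max_iters = 50))
  filled <- predict_missing_blocks(m, ms)
  expect_equal(dim(filled), dim(ms$values))
  expect_identical(filled[ms$observed_mask], ms$values[ms$observed_mask])
  expect_true(all(filled >= 0))
  # top rows: component 3 undetermined there, but its fluorescence signal is
  # zero anyway, so the hidden fluorescence block is still reproduced;
  # bottom rows lose nothing because all components carry Raman signal
  expect_equal(filled[41:55, 1:8], V_full[41:55, 1:8], tolerance = 1e-6)
})
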