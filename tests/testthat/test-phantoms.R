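test_that("phantom maps are reproducible, contained and covering", {
  spec <- phantom_spec(seed = 60)
  m1 <- generate_phantom_maps(spec)
  m2 <- generate_phantom_maps(spec)
  expect_identical(m1, m2)

  expect_true(all(m1 >= 0 & m1 <= 1))
  # nucleolus strictly inside the nucleus support (nucleus was carved where
  # the nucleolus sits, so test against the un-carved union)
  nuc_support <- (m1[, , "nucleus"] + m1[, , "nucleolus"]) > 0
  expect_true(all(nuc_support[m1[, , "nucleolus"] > 0]))
  # full coverage: some component is present at every pixel
  total <- apply(m1, c(1, 2), sum)
  expect_true(all(total > 0))

  expect_error(phantom_spec(rows = 20, cols = 20), "too small")
})

test_that("pure spectra have the configured structure", {
  spec <- phantom_spec(seed = 61)
  Sf <- generate_pure_spectra(spec, "fluorescence")
  expect_equal(ncol(Sf), 57)                       # 415-695 nm at 5 nm
  expect_equal(length(spec$fluor_axis), (695 - 415) / 5 + 1)
  fl <- spec$components$fluorescent
  expect_equal(sum(fl), 3)
  expect_true(all(Sf[!fl, ] == 0))                 # exact nulls
  expect_equal(unname(sqrt(rowSums(Sf[fl, ]^2))), rep(1, 3),
               tolerance = 1e-9)

  Sr <- generate_pure_spectra(spec, "raman")
  expect_true(all(Sr >= 0))
  expect_equal(unname(sqrt(rowSums(Sr^2))), rep(1, 6), tolerance = 1e-9)
  cc <- cor(t(Sr))
  od <- cc[upper.tri(cc)]
  expect_true(all(od >= 0.25 & od <= 0.85))        # overlapping signatures
})

test_that("the forward model is exact at zero noise and calibrated with it", {
  spec0 <- phantom_spec(seed = 62, noise_sd = 0)
  maps <- generate_phantom_maps(spec0)[1:10, 1:10, , drop = FALSE]
  Sf <- generate_pure_spectra(spec0, "fluorescence")
  cube0 <- simulate_measurement(maps, Sf, spec0, "fluorescence")
  expect_equal(unfold(cube0), maps_to_C(maps) %*% Sf, tolerance = 1e-12)
  expect_equal(attr(cube0, "n_spikes"), 0L)

  spec1 <- phantom_spec(seed = 62, noise_sd = 0.03)
  cube1 <- simulate_measurement(maps, Sf, spec1, "fluorescence")
  resid <- unfold(cube1) - maps_to_C(maps) %*% Sf
  target <- 0.03 * max(maps_to_C(maps) %*% Sf)
  expect_equal(sd(resid), target, tolerance = 0.05)

  spec2 <- phantom_spec(seed = 62, noise_sd = 0, spike_rate = 1e-3)
  Sr <- generate_pure_spectra(spec2, "raman")
  cube2 <- simulate_measurement(maps, Sr, spec2, "raman")
  n <- attr(cube2, "n_spikes")
  expect_gt(n, 0)
  expect_lt(abs(n - 1e-3 * 100 * 556), 4 * sqrt(1e-3 * 100 * 556))
})

test_that("the default scenario mirrors the five-cell, four-subarea layout", {
  sc <- build_fusion_scenario(phantom_spec(seed = 63))
  expect_length(sc$fluor_cubes, 5)
  expect_named(sc$raman_cubes, c("r4A", "r4B", "r5A", "r5B"))
  expect_equal(vapply(sc$truth$regions, function(r) r$cell, 0L),
               c(r4A = 4L, r4B = 4L, r5A = 5L, r5B = 5L))
  # nucleolus absent from the areas scanned on cell 4, present on cell 5
  sub <- sc$truth$spec$subregion
  for (nm in names(sc$truth$regions)) {
    r <- sc$truth$regions[[nm]]
    win <- sc$truth$maps[[r$cell]][r$actual[1]:(r$actual[1] + sub - 1),
                                   r$actual[2]:(r$actual[2] + sub - 1), 2]
    if (r$cell == 4) expect_equal(sum(win), 0) else expect_gt(sum(win), 1)
  }
  # scenario is reproducible from its seed
  sc2 <- build_fusion_scenario(phantom_spec(seed = 63))
  expect_identical(sc$truth, sc2$truth)
  expect_identical(sc$fluor_cubes[[3]]$data, sc2$fluor_cubes[[3]]$data)
})

test_that("planted offsets are recovered from ground-truth droplet maps", {
  sc <- build_fusion_scenario(phantom_spec(seed = 64, noise_sd = 0))
  sub <- sc$truth$spec$subregion
  for (nm in names(sc$truth$regions)) {
    r <- sc$truth$regions[[nm]]
    maps <- sc$truth$maps[[r$cell]]
    ref <- bin_spatial(hsi_cube(maps[r$nominal[1]:(r$nominal[1] + sub - 1),
                                     r$nominal[2]:(r$nominal[2] + sub - 1),
                                     4, drop = FALSE],
                                1, "nm", 0.2, "m"), 4)$data[, , 1]
    mov <- bin_spatial(hsi_cube(maps[r$actual[1]:(r$actual[1] + sub - 1),
                                     r$actual[2]:(r$actual[2] + sub - 1),
                                     4, drop = FALSE],
                                1, "nm", 0.2, "m"), 4)$data[, , 1]
    est <- estimate_rigid_transform(ref, mov, 3, 0)
    # moving window sits at nominal + shift, so undoing the estimated
    # transform must land back on the actual window
    rec <- r$nominal - 4 * c(est$transform$d_row, est$transform$d_col)
    expect_equal(rec, r$actual, ignore_attr = TRUE)
  }
})
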