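#' Specification of a labeled-cell phantom
#'
#' Parameters of the synthetic ground-truth scenario: a cell with six
#' constituents (nucleus, nucleolus, cytoskeleton, lipid droplets,
#' protein-enriched perinuclear region, sample support), of which exactly
#' three are fluorescent (nucleus, cytoskeleton, lipid droplets — mimicking
#' DAPI-, phalloidin- and lipid-dye labeling); the other three have null
#' fluorescence signal. Measurements are simulated at 0.2 um pixel size with
#' a 57-channel fluorescence emission axis (415-695 nm, 5 nm steps) and a
#' 556-channel Raman axis (640-1750 cm^-1, 2 cm^-1 steps).
#'
#' @param rows,cols Canvas size in native pixels (>= 48; the default 96 px at 0.2 um spans a whole cell).
#' @param seed Integer seed; every generator operation is reproducible
#'   from it.
#' @param pixel_size Native pixel edge in micrometres.
#' @param noise_sd Additive Gaussian noise standard deviation, as a fraction
#'   of the maximum clean intensity of the simulated cube.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (photon-counting
#'   realism for fluorescence; `noise_sd` then scales the expected counts as
#'   `counts = signal / noise_sd^2`).
#' @param baseline_amplitude Raman baseline amplitude as a fraction of the
#'   maximum clean intensity (0 disables).
#' @param spike_rate Cosmic-spike probability per (pixel, channel) in Raman
#'   simulation.
#' @param n_droplets,n_filaments Structure counts.
#' @param subregion Side length (native px, multiple of 4) of the small
#'   Raman scan areas in [build_fusion_scenario()].
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 96L, cols = 96L, seed = 1L, pixel_size = 0.2,
                         noise_sd = 0.02, noise_model = c("gaussian", "poisson"),
                         baseline_amplitude = 0, spike_rate = 0,
                         n_droplets = 8L, n_filaments = 5L, subregion = 32L) {
  noise_model <- match.arg(noise_model)
  if (rows < 48L || cols < 48L)
    stop("canvas too small to place the cell structures (need >= 48 px)")
  if (subregion %% 4L != 0L || subregion < 16L)
    stop("subregion must be a multiple of 4 and at least 16")
  if (subregion + 16L > min(rows, cols))
    stop("subregion does not fit inside the canvas with the alignment margin")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 seed = as.integer(seed), pixel_size = pixel_size,
                 noise_sd = noise_sd, noise_model = noise_model,
                 baseline_amplitude = baseline_amplitude,
                 spike_rate = spike_rate, n_droplets = as.integer(n_droplets),
                 n_filaments = as.integer(n_filaments),
                 subregion = as.integer(subregion),
                 components = data.frame(
                   role = c("nucleus", "nucleolus", "cytoskeleton",
                            "droplets", "protein", "support"),
                   fluorescent = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)),
                 fluor_axis = seq(415, 695, by = 5),
                 raman_axis = seq(640, 1750, by = 2)),
            class = "phantom_spec")
}

# smooth-edged ellipse on the pixel grid
.ellipse <- function(rows, cols, cr, cc, a, b, edge = 1.5) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  d <- sqrt(((r - cr) / a)^2 + ((c - cc) / b)^2)
  pmin(pmax((1 - d) / (edge / min(a, b)) , 0), 1)
}

#' Generate ground-truth component distribution maps
#'
#' Deterministic (seeded) morphology: the nucleus is a smooth ellipse, the
#' nucleolus a small blob strictly inside it, lipid droplets are scattered
#' discs in the cytoplasm, the cytoskeleton a set of filament strokes, the
#' protein-enriched component a perinuclear ring, and the support the
#' complement covering all background pixels. Maps lie in `[0, 1]`, their
#' sum is positive at every pixel, and each component has near-pure pixels
#' (structures are carved out of one another where they overlap).
#'
#' @param spec A [phantom_spec].
#' @return `rows x cols x 6` array; component order follows
#'   `spec$components$role`.
#' @export
generate_phantom_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$rows; nc <- spec$cols
  cell <- .ellipse(nr, nc, nr / 2 + stats::runif(1, -2, 2),
                   nc / 2 + stats::runif(1, -2, 2),
                   0.44 * nr, 0.42 * nc, edge = 3)
  ncr <- nr / 2 + stats::runif(1, -0.08, 0.08) * nr
  ncc <- nc / 2 + stats::runif(1, -0.08, 0.08) * nc
  na_ <- 0.17 * nr; nb <- 0.15 * nc
  nucleus <- .ellipse(nr, nc, ncr, ncc, na_, nb, edge = 2)
  nucleolus <- .ellipse(nr, nc, ncr - 0.35 * na_, ncc - 0.35 * nb,
                        0.3 * na_, 0.3 * nb, edge = 1.2)
  nucleolus <- nucleolus * (nucleus > 0)          # strictly inside the nucleus
  nucleus <- nucleus * (1 - nucleolus)
  # perinuclear protein-enriched ring
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dn <- sqrt(((rg - ncr) / na_)^2 + ((cg - ncc) / nb)^2)
  ring <- exp(-((dn - 1.35) / 0.22)^2) * cell * (nucleus < 0.05)
  # lipid droplets: discs in the cytoplasm, away from the nucleus
  droplets <- matrix(0, nr, nc)
  placed <- 0L; tries <- 0L
  while (placed < spec$n_droplets && tries < 500L) {
    tries <- tries + 1L
    pr <- stats::runif(1, 6, nr - 5); pc <- stats::runif(1, 6, nc - 5)
    dcand <- sqrt(((rg - pr))^2 + ((cg - pc))^2)
    here <- dn[round(pr), round(pc)]
    if (here < 1.15 || cell[round(pr), round(pc)] < 0.5) next
    rad <- stats::runif(1, 1.8, 3.0)
    droplets <- pmax(droplets, pmin(pmax((rad - dcand) / 0.8 + 1, 0), 1))
    placed <- placed + 1L
  }
  droplets <- droplets * cell
  # cytoskeleton: filament strokes crossing the cytoplasm
  cyto <- matrix(0, nr, nc)
  for (f in seq_len(spec$n_filaments)) {
    th <- stats::runif(1, 0, pi)
    off <- stats::runif(1, -0.3, 0.3) * min(nr, nc)
    dist_line <- abs((rg - nr / 2) * cos(th) + (cg - nc / 2) * sin(th) - off)
    cyto <- pmax(cyto, exp(-(dist_line / 1.1)^2))
  }
  cyto <- cyto * cell * (nucleus < 0.05) * (1 - ring) * (1 - droplets)
  ring <- ring * (1 - droplets)
  support <- pmax(0, 1 - (nucleus + nucleolus + cyto + droplets + ring))
  maps <- array(0, c(nr, nc, 6L))
  maps[, , 1] <- nucleus; maps[, , 2] <- nucleolus; maps[, , 3] <- cyto
  maps[, , 4] <- droplets; maps[, , 5] <- ring; maps[, , 6] <- support
  dimnames(maps) <- list(NULL, NULL, spec$components$role)
  maps
}

.gauss_band <- function(x, pos, width) exp(-((x - pos) / width)^2)
.lorentz_band <- function(x, pos, width) 1 / (1 + ((x - pos) / width)^2)

#' Generate ground-truth pure spectra
#'
#' Fluorescence: one broad Gaussian emission band per fluorescent component
#' (nucleus, cytoskeleton, lipid droplets) with slightly jittered centres;
#' exact zeros for the three non-fluorescent components. Raman: 3-8 positive
#' Lorentzian/Gaussian bands per component at seeded positions, blended with
#' a common profile so that pairwise spectral correlations fall in the
#' 0.3-0.8 range (overlapping signatures make the unmixing realistic rather
#' than trivial). All spectra are non-negative with unit Euclidean norm
#' (zero rows excepted).
#'
#' @param spec A [phantom_spec].
#' @param modality `"fluorescence"` or `"raman"`.
#' @return 6 x channels matrix, rows ordered as `spec$components$role`.
#' @export
generate_pure_spectra <- function(spec, modality = c("fluorescence", "raman")) {
  stopifnot(inherits(spec, "phantom_spec"))
  modality <- match.arg(modality)
  set.seed(spec$seed + 1000L)
  roles <- spec$components$role
  if (modality == "fluorescence") {
    x <- spec$fluor_axis
    S <- matrix(0, 6L, length(x), dimnames = list(roles, NULL))
    centers <- c(nucleus = 455, cytoskeleton = 545, droplets = 490) +
      stats::runif(3, -5, 5)
    widths <- c(24, 30, 19)
    for (i in seq_along(centers)) {
      k <- match(names(centers)[i], roles)
      S[k, ] <- .gauss_band(x, centers[i], widths[i])
    }
  } else {
    x <- spec$raman_axis
    S <- matrix(0, 6L, length(x), dimnames = list(roles, NULL))
    common <- .gauss_band(x, 1004, 60) + 0.7 * .lorentz_band(x, 1450, 50) +
      0.5 * .gauss_band(x, 1660, 45)
    uniq <- matrix(0, 6L, length(x))
    for (k in 1:6) {
      nb <- sample(3:8, 1)
      pos <- stats::runif(nb, 660, 1730)
      wid <- stats::runif(nb, 8, 25)
      amp <- stats::runif(nb, 0.3, 1)
      lor <- stats::runif(nb) < 0.5
      for (b in seq_len(nb))
        uniq[k, ] <- uniq[k, ] + amp[b] *
          if (lor[b]) .lorentz_band(x, pos[b], wid[b])
          else .gauss_band(x, pos[b], wid[b])
      uniq[k, ] <- uniq[k, ] / max(uniq[k, ])
    }
    w <- 0.4
    for (adjust in 1:40) {
      S <- (1 - w) * uniq + w * matrix(common / max(common), 6L, length(x),
                                       byrow = TRUE)
      cc <- stats::cor(t(S))
      od <- cc[upper.tri(cc)]
      if (min(od) < 0.3) w <- w + 0.03
      else if (max(od) > 0.8) w <- w - 0.03
      else break
      w <- min(max(w, 0.02), 0.9)
    }
    dimnames(S) <- list(roles, NULL)
  }
  nrm <- sqrt(rowSums(S^2))
  S[nrm > 0, ] <- S[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  S
}

#' Simulate a hyperspectral measurement of a phantom
#'
#' Forward bilinear model: each pixel spectrum is the concentration-weighted
#' sum of the pure spectra, plus (for Raman) a smooth positive baseline
#' scaled by `baseline_amplitude`, additive noise, and cosmic spikes at the
#' configured rate. At zero noise, zero baseline and zero spike rate the
#' unfolded cube equals `C %*% S` exactly.
#'
#' @param maps `rows x cols x n` ground-truth concentration array.
#' @param spectra `n x channels` pure spectra.
#' @param spec A [phantom_spec] (noise/baseline/spike settings and axes).
#' @param modality `"fluorescence"` or `"raman"`.
#' @param seed_offset Integer added to `spec$seed` so that different
#'   measurements of one scenario draw independent noise.
#' @return An [hsi_cube]; attribute `"n_spikes"` records the number of
#'   cosmic spikes actually planted.
#' @export
simulate_measurement <- function(maps, spectra, spec,
                                 modality = c("fluorescence", "raman"),
                                 seed_offset = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  modality <- match.arg(modality)
  d <- dim(maps)
  stopifnot(length(d) == 3L, d[3L] == nrow(spectra))
  C <- matrix(aperm(maps, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  D <- C %*% spectra
  top <- max(D)
  set.seed(spec$seed + 2000L + seed_offset)
  n_spikes <- 0L
  if (modality == "raman" && spec$baseline_amplitude > 0) {
    x <- seq(0, 1, length.out = ncol(D))
    shape <- exp(-2.5 * x) + 0.3 * (1 - x)^2
    percel <- stats::runif(nrow(D), 0.7, 1.3)
    D <- D + spec$baseline_amplitude * top * outer(percel, shape)
  }
  if (spec$noise_sd > 0) {
    if (spec$noise_model == "poisson") {
      scale <- 1 / (spec$noise_sd^2 * top)
      D <- matrix(stats::rpois(length(D), pmax(D, 0) * scale) / scale, nrow(D))
    } else {
      D <- D + matrix(stats::rnorm(length(D), 0, spec$noise_sd * top), nrow(D))
    }
  }
  if (modality == "raman" && spec$spike_rate > 0) {
    hit <- which(stats::runif(length(D)) < spec$spike_rate)
    n_spikes <- length(hit)
    D[hit] <- D[hit] + stats::runif(n_spikes, 5, 15) * top
  }
  axis <- if (modality == "fluorescence") spec$fluor_axis else spec$raman_axis
  unit <- if (modality == "fluorescence") "nm" else "cm-1"
  cube <- hsi_cube(refold(D, d[1:2]), axis, unit, spec$pixel_size, modality)
  attr(cube, "n_spikes") <- n_spikes
  cube
}

# choose a subregion window: scans a coarse grid of top-left corners,
# scoring structural content, subject to presence/absence of the nucleolus
.pick_region <- function(maps, size, need_nucleolus, avoid = NULL, margin = 8L) {
  nr <- dim(maps)[1]; nc <- dim(maps)[2]
  best <- NULL; best_score <- -Inf
  for (r in seq(margin + 1L, nr - size - margin + 1L, by = 4L)) {
    for (c in seq(margin + 1L, nc - size - margin + 1L, by = 4L)) {
      win <- function(k) maps[r:(r + size - 1L), c:(c + size - 1L), k]
      nlo <- sum(win(2))
      if (need_nucleolus && nlo < 1) next
      if (!need_nucleolus && nlo > 0) next
      if (!is.null(avoid)) {
        ov <- max(0, min(r + size, avoid[1] + size) - max(r, avoid[1])) *
          max(0, min(c + size, avoid[2] + size) - max(c, avoid[2]))
        if (ov > 0.4 * size^2) next
      }
      score <- 2 * sum(win(4)) + sum(win(3)) + 0.5 * sum(win(5)) +
        0.3 * sum(win(1))
      if (sum(win(4)) < 2) next                    # droplets anchor alignment
      if (score > best_score) { best_score <- score; best <- c(r, c) }
    }
  }
  if (is.null(best))
    stop("no admissible subregion window found (canvas too small or ",
         "structures unluckily placed for this seed)")
  best
}

#' Build the full multimodal fusion scenario with hidden ground truth
#'
#' Generates the study layout: five whole-cell fluorescence images (cells
#' 1-5) and four small-area Raman images (two subregions on each of cells 4
#' and 5, analogous to areas 4A/4B/5A/5B). Raman subregions are crops of the
#' phantom at a planted rigid offset (an integer shift, multiple of 4 native
#' pixels, so it is an integer shift on the common downsampled grid) from
#' the nominal crop window. The subregions on cell 4 are placed where the
#' nucleolus is absent — the basis of the correspondence-of-species
#' constraint — while those on cell 5 contain it. A ground-truth bundle
#' (maps, spectra, planted transforms, regions) is returned for scoring and
#' is never needed by the fitting pipeline.
#'
#' @param spec A [phantom_spec].
#' @return List with `fluor_cubes` (5 whole-cell [hsi_cube]s),
#'   `raman_cubes` (named list `r4A`, `r4B`, `r5A`, `r5B`), and `truth`
#'   (maps per cell, pure spectra per modality, nominal and actual crop
#'   windows, planted shifts on the native and binned grids, the spec).
#' @export
build_fusion_scenario <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  S_f <- generate_pure_spectra(spec, "fluorescence")
  S_r <- generate_pure_spectra(spec, "raman")
  cells <- lapply(1:5, function(i) {
    sp <- spec; sp$seed <- spec$seed + 10L * i
    generate_phantom_maps(sp)
  })
  fluor_cubes <- lapply(1:5, function(i)
    simulate_measurement(cells[[i]], S_f, spec, "fluorescence",
                         seed_offset = i))
  sub <- spec$subregion
  set.seed(spec$seed + 3000L)
  regions <- list(); shifts <- list(); raman_cubes <- list()
  layout <- list(r4A = list(cell = 4L, need_nucleolus = FALSE),
                 r4B = list(cell = 4L, need_nucleolus = FALSE),
                 r5A = list(cell = 5L, need_nucleolus = TRUE),
                 r5B = list(cell = 5L, need_nucleolus = TRUE))
  prev <- list(r4A = NULL, r4B = "r4A", r5A = NULL, r5B = "r5A")
  for (nm in names(layout)) {
    li <- layout[[nm]]
    avoid <- if (!is.null(prev[[nm]])) regions[[prev[[nm]]]]$actual else NULL
    # constraints (nucleolus presence/absence, droplet content) must hold for
    # the window the Raman instrument actually scans, so pick that window and
    # derive the nominal aim point by undoing the planted offset
    shift <- sample(c(-8L, -4L, 0L, 4L, 8L), 2L, replace = TRUE)
    actual <- .pick_region(cells[[li$cell]], sub, li$need_nucleolus, avoid)
    nominal <- actual - shift
    regions[[nm]] <- list(cell = li$cell, nominal = nominal, actual = actual)
    shifts[[nm]] <- shift
    sub_maps <- cells[[li$cell]][actual[1]:(actual[1] + sub - 1L),
                                 actual[2]:(actual[2] + sub - 1L), ,
                                 drop = FALSE]
    raman_cubes[[nm]] <- simulate_measurement(sub_maps, S_r, spec, "raman",
                                              seed_offset = 100L + match(nm, names(layout)))
  }
  list(fluor_cubes = fluor_cubes, raman_cubes = raman_cubes,
       truth = list(maps = cells, spectra_fluor = S_f, spectra_raman = S_r,
                    regions = regions, shifts_native = shifts,
                    shifts_binned = lapply(shifts, function(s) s / 4L),
                    spec = spec))
}

# unfold a ground-truth map array into a concentration matrix
.maps_to_C <- function(maps) {
  d <- dim(maps)
  matrix(aperm(maps, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

# spatially bin a map stack by summation (matches how binned measurements
# aggregate the underlying concentrations)
.bin_maps <- function(maps, factor) {
  cube <- hsi_cube(maps, seq_len(dim(maps)[3]), "nm", 1, "maps")
  bin_spatial(cube, factor)$data
}
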