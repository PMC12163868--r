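#' Per-modality multiset analyses of a fusion scenario
#'
#' Runs the two preliminary complete-data unmixings that precede image
#' fusion: the column-wise augmented fluorescence multiset (all whole-cell
#' images, binned) and the column-wise augmented Raman multiset (all native
#' small-area images). Their distribution maps provide the references for
#' co-registration and their pure spectra the initial estimates of the
#' incomplete-multiset run.
#'
#' @param fluor_cubes List of whole-cell fluorescence [hsi_cube]s.
#' @param raman_cubes Named list of small-area Raman [hsi_cube]s.
#' @param n_fluor,n_raman Number of components per modality.
#' @param fluor_bin Binning factor applied to the fluorescence images before
#'   analysis.
#' @param constraints A [constraint_set] used for both runs.
#' @param convergence A [convergence_spec].
#' @return List with `fluor` and `raman`, each holding `model` (the
#'   [mcr_model]), `shapes` (image shapes after any binning) and `rows`
#'   (row ranges per image in the stacked matrix).
#' @export
modality_models <- function(fluor_cubes, raman_cubes, n_fluor = 3L,
                            n_raman = 6L, fluor_bin = 2L,
                            constraints = constraint_set(),
                            convergence = convergence_spec()) {
  fit_stack <- function(cubes, n) {
    mats <- lapply(cubes, unfold)
    D <- do.call(rbind, mats)
    rows <- list(); off <- 0L
    shapes <- lapply(cubes, function(cb) dim(cb$data)[1:2])
    for (i in seq_along(mats)) {
      rows[[i]] <- (off + 1L):(off + nrow(mats[[i]]))
      off <- off + nrow(mats[[i]])
    }
    names(rows) <- names(shapes) <- names(cubes)
    S0 <- simplisma_initial_spectra(D, n)
    list(model = run_mcr_als(D, S0 = S0, constraints = constraints,
                             convergence = convergence),
         shapes = shapes, rows = rows)
  }
  fl_binned <- lapply(fluor_cubes, bin_spatial, factor = fluor_bin)
  names(fl_binned) <- names(fluor_cubes) %||% paste0("cell", seq_along(fluor_cubes))
  list(fluor = fit_stack(fl_binned, n_fluor),
       raman = fit_stack(raman_cubes, n_raman))
}

# component distribution maps of one image from a stacked modality model
.model_maps <- function(fit, image) {
  C <- fit$model$C[fit$rows[[image]], , drop = FALSE]
  refold(C, fit$shapes[[image]])
}

#' Co-register one Raman subregion against its parent fluorescence image
#'
#' Follows the reference-map strategy: candidate reference maps are the
#' per-modality MCR distribution maps brought to the common (coarse) pixel
#' grid; the transform is estimated for every (fluorescence component,
#' Raman component) map pair and the pair attaining the highest normalized
#' cross-correlation wins — in practice the constituent with the most
#' distinctive spatial pattern (typically the lipid droplets) selects
#' itself. Both modalities are binned to the common grid before estimation.
#'
#' @param fits Output of [modality_models()].
#' @param fluor_image Name/index of the whole-cell fluorescence image.
#' @param raman_image Name of the Raman subregion image.
#' @param nominal `c(top, left)` native-pixel corner of the window the
#'   Raman scan was aimed at.
#' @param subregion Native-pixel side length of the Raman scan.
#' @param fluor_bin Binning already applied to the fluorescence model grid.
#' @param core_bin Total native-to-common-grid binning factor.
#' @param shift_bound,theta_bound,theta_step Search bounds passed to
#'   [estimate_rigid_transform()].
#' @return List with `transform`, `score`, `pair` (winning component pair)
#'   and `corrected` (native-pixel corner such that cropping there matches
#'   the Raman area; meaningful for integer-shift alignments).
#' @export
register_subregion <- function(fits, fluor_image, raman_image, nominal,
                               subregion, fluor_bin = 2L, core_bin = 4L,
                               shift_bound = 3L, theta_bound = 0,
                               theta_step = 0.5) {
  fb <- core_bin %/% fluor_bin
  fl_maps <- .model_maps(fits$fluor, fluor_image)
  rm_maps <- .model_maps(fits$raman, raman_image)
  r2 <- (nominal[1] - 1L) %/% fluor_bin + 1L
  c2 <- (nominal[2] - 1L) %/% fluor_bin + 1L
  side2 <- subregion %/% fluor_bin
  best <- NULL
  for (i in seq_len(dim(fl_maps)[3])) {
    ref <- .bin_maps(fl_maps[r2:(r2 + side2 - 1L), c2:(c2 + side2 - 1L), i,
                             drop = FALSE], fb)[, , 1]
    if (stats::sd(ref) == 0) next
    for (j in seq_len(dim(rm_maps)[3])) {
      mov <- .bin_maps(rm_maps[, , j, drop = FALSE], core_bin)[, , 1]
      if (stats::sd(mov) == 0) next
      est <- estimate_rigid_transform(ref, mov, shift_bound, theta_bound,
                                      theta_step)
      if (is.null(best) || est$score > best$score)
        best <- list(transform = est$transform, score = est$score,
                     pair = c(fluor = i, raman = j))
    }
  }
  if (is.null(best)) stop("no usable reference map pair for registration")
  best$corrected <- c(nominal[1] - core_bin * best$transform$d_row,
                      nominal[2] - core_bin * best$transform$d_col)
  best
}

#' Fuse, assemble and initialize an incomplete multiset from a scenario
#'
#' The full pre-analysis pipeline: per-modality MCR runs, co-registration of
#' every Raman subregion, construction of the fused core on the common
#' coarse grid, assembly of the incomplete multiset (whole-cell fluorescence
#' on top, fused core in the middle, native-resolution Raman at the bottom),
#' pairing of fluorescence and Raman components through their core-area
#' distribution maps, construction of the combined initial spectra, and
#' derivation of the equality constraints (null fluorescence segments for
#' unpaired Raman components; correspondence of species for components
#' absent from specific subregions, detected from the per-modality Raman
#' concentrations).
#'
#' @param fluor_cubes List of 5 whole-cell fluorescence cubes (cells 1-5);
#'   by convention the last cell's full image is not appended to the
#'   multiset when it already contributes fused subregions.
#' @param raman_cubes Named list of Raman subregion cubes.
#' @param regions Named list (parallel to `raman_cubes`): each entry a list
#'   with `cell` (index into `fluor_cubes`) and `nominal` (`c(top, left)`
#'   native corner of the aimed window). Acquisition metadata only — the
#'   true offsets are estimated, never read.
#' @param top_cells Indices of whole-cell fluorescence images appended on
#'   top of the multiset (default all but the last).
#' @param n_fluor,n_raman Component counts per modality.
#' @param fluor_bin Whole-cell fluorescence binning factor (common top-block
#'   grid).
#' @param core_bin Native-to-fused-core binning factor.
#' @param shift_bound,theta_bound Registration search bounds.
#' @param absent_tol A component whose robust peak concentration within a Raman
#'   image falls below `absent_tol` times its maximum over all Raman images is declared
#'   absent there (correspondence of species).
#' @param constraints_modality [constraint_set] for the per-modality runs.
#' @param convergence [convergence_spec] for the per-modality runs.
#' @return List with `ms` (the [multiset_matrix]), `S0` (combined initial
#'   spectra), `constraints` (the derived [constraint_set]),
#'   `registrations`, `pairs` (fluorescence-to-Raman component assignment),
#'   `fits` (per-modality models) and `layout` bookkeeping.
#' @export
fuse_and_assemble <- function(fluor_cubes, raman_cubes, regions,
                              top_cells = NULL,
                              n_fluor = 3L, n_raman = 6L, fluor_bin = 2L,
                              core_bin = 4L, shift_bound = 3L,
                              theta_bound = 0, absent_tol = 0.15,
                              constraints_modality = constraint_set(),
                              convergence = convergence_spec()) {
  stopifnot(length(raman_cubes) == length(regions))
  nms <- names(raman_cubes)
  if (is.null(top_cells)) top_cells <- seq_len(length(fluor_cubes) - 1L)
  fits <- modality_models(fluor_cubes, raman_cubes, n_fluor, n_raman,
                          fluor_bin, constraints_modality, convergence)
  sub <- dim(raman_cubes[[1]]$data)[1L]
  registrations <- list()
  core_blocks_f <- list(); core_blocks_r <- list()
  core_rb <- list(); off <- 0L
  for (nm in nms) {
    reg <- regions[[nm]]
    est <- register_subregion(fits, reg$cell, nm, reg$nominal, sub,
                              fluor_bin, core_bin, shift_bound, theta_bound)
    registrations[[nm]] <- est
    fl_crop <- crop_to_region(fluor_cubes[[reg$cell]], est$corrected[1],
                              est$corrected[2], sub, sub)
    flb <- bin_spatial(fl_crop, core_bin)
    rb <- bin_spatial(raman_cubes[[nm]], core_bin)
    core_blocks_f[[nm]] <- unfold(flb)
    core_blocks_r[[nm]] <- unfold(rb)
    npx <- nrow(core_blocks_f[[nm]])
    core_rb[[nm]] <- list(id = paste0("core_", nm), rows = (off + 1L):(off + npx),
                          source = nm, shape = dim(flb$data)[1:2])
    off <- off + npx
  }
  fluor_axis <- fluor_cubes[[1]]$spectral_axis
  raman_axis <- raman_cubes[[1]]$spectral_axis
  fused <- fuse_rowwise(list(fluorescence = do.call(rbind, core_blocks_f),
                             raman = do.call(rbind, core_blocks_r)),
                        spectral_axes = list(fluor_axis, raman_axis))
  fused$row_blocks <- core_rb
  top <- lapply(top_cells, function(i) {
    cb <- bin_spatial(fluor_cubes[[i]], fluor_bin)
    list(values = unfold(cb), modality = "fluorescence",
         id = paste0("fluo_cell", i), source = i, shape = dim(cb$data)[1:2])
  })
  bottom <- lapply(nms, function(nm) {
    list(values = unfold(raman_cubes[[nm]]), modality = "raman",
         id = paste0("raman_", nm), source = nm,
         shape = dim(raman_cubes[[nm]]$data)[1:2])
  })
  ms <- assemble_incomplete_multiset(fused, c(top, bottom))

  # pair fluorescence components with Raman components through their
  # distribution maps over the fused core area
  pairs <- .pair_components(fits, registrations, regions, sub, fluor_bin,
                            core_bin, n_fluor, n_raman)
  S_f <- fits$fluor$model$S_t
  S_r <- fits$raman$model$S_t
  S0 <- matrix(0, n_raman, length(fluor_axis) + length(raman_axis))
  S0[, length(fluor_axis) + seq_along(raman_axis)] <- S_r
  for (i in seq_len(n_fluor))
    S0[pairs[i], seq_along(fluor_axis)] <- S_f[i, ]
  null_fluor <- setdiff(seq_len(n_raman), pairs)

  # correspondence of species: components absent from specific Raman areas.
  # A robust per-area peak (mean of the brightest pixels) separates genuine
  # presence — even of sparse structures like lipid droplets — from the
  # diffuse low-level leakage that rotational ambiguity spreads into areas
  # where a constituent is absent.
  blk_peak <- sapply(nms, function(nm)
    apply(fits$raman$model$C[fits$raman$rows[[nm]], , drop = FALSE], 2L,
          function(v) mean(sort(v, decreasing = TRUE)[1:min(8L, length(v))])))
  zero_C <- list()
  for (comp in seq_len(n_raman)) {
    mx <- max(blk_peak[comp, ])
    absent <- nms[blk_peak[comp, ] < absent_tol * mx]
    for (nm in absent)
      zero_C <- c(zero_C, list(c(paste0("core_", nm), comp)),
                  list(c(paste0("raman_", nm), comp)))
  }
  constraints <- constraint_set(
    nonneg_C = TRUE, nonneg_S = TRUE,
    zero_C_blocks = zero_C,
    zero_S_segments = lapply(null_fluor, function(k) c(k, "fluorescence")),
    nonneg_mode = "nnls")
  list(ms = ms, S0 = S0, constraints = constraints,
       registrations = registrations, pairs = pairs, fits = fits,
       layout = list(top_cells = top_cells, regions = regions,
                     fluor_bin = fluor_bin, core_bin = core_bin,
                     subregion = sub))
}

# assign each fluorescence component to a distinct Raman component by
# maximizing total correlation of their core-area maps on the common grid
.pair_components <- function(fits, registrations, regions, sub, fluor_bin,
                             core_bin, n_fluor, n_raman) {
  fb <- core_bin %/% fluor_bin
  fmaps <- vector("list", n_fluor); rmaps <- vector("list", n_raman)
  for (nm in names(regions)) {
    reg <- regions[[nm]]
    corr <- registrations[[nm]]$corrected
    r2 <- (corr[1] - 1L) %/% fluor_bin + 1L
    c2 <- (corr[2] - 1L) %/% fluor_bin + 1L
    side2 <- sub %/% fluor_bin
    fl <- .model_maps(fits$fluor, reg$cell)
    rm_ <- .model_maps(fits$raman, nm)
    for (i in seq_len(n_fluor))
      fmaps[[i]] <- c(fmaps[[i]],
                      as.vector(.bin_maps(fl[r2:(r2 + side2 - 1L),
                                             c2:(c2 + side2 - 1L), i,
                                             drop = FALSE], fb)))
    for (j in seq_len(n_raman))
      rmaps[[j]] <- c(rmaps[[j]],
                      as.vector(.bin_maps(rm_[, , j, drop = FALSE], core_bin)))
  }
  corr_mat <- matrix(-1, n_fluor, n_raman)
  for (i in seq_len(n_fluor)) for (j in seq_len(n_raman)) {
    if (stats::sd(fmaps[[i]]) > 0 && stats::sd(rmaps[[j]]) > 0)
      corr_mat[i, j] <- stats::cor(fmaps[[i]], rmaps[[j]])
  }
  combos <- utils::combn(n_raman, n_fluor)
  perms <- .permutations(n_fluor)
  best <- NULL; best_tot <- -Inf
  for (ci in seq_len(ncol(combos))) for (pi in seq_len(nrow(perms))) {
    asg <- combos[perms[pi, ], ci]
    tot <- sum(corr_mat[cbind(seq_len(n_fluor), asg)])
    if (tot > best_tot) { best_tot <- tot; best <- asg }
  }
  best
}

#' Fit the incomplete multiset of a synthetic fusion scenario
#'
#' Convenience end-to-end driver for a [build_fusion_scenario()] output:
#' runs [fuse_and_assemble()] on the measured cubes and the nominal-window
#' metadata, then [run_incomplete_mcr()] with the derived initial estimates
#' and constraints.
#'
#' @param scenario Output of [build_fusion_scenario()].
#' @param convergence A [convergence_spec].
#' @param ... Passed to [fuse_and_assemble()].
#' @return The [fuse_and_assemble()] list, extended with `model` (the
#'   fitted [mcr_model]).
#' @export
fit_fusion_scenario <- function(scenario, convergence = convergence_spec(),
                                ...) {
  regions <- lapply(scenario$truth$regions, function(r)
    list(cell = r$cell, nominal = r$nominal))
  fa <- fuse_and_assemble(scenario$fluor_cubes, scenario$raman_cubes,
                          regions, convergence = convergence, ...)
  fa$model <- run_incomplete_mcr(fa$ms, fa$S0, fa$constraints, convergence)
  fa
}

#' Score a fitted scenario model against the hidden ground truth
#'
#' Matches model components to ground-truth constituents by maximizing the
#' total cosine similarity of the augmented spectra, then reports the cosine
#' similarity of every matched spectrum and of every matched concentration
#' map (evaluated over the multiset rows, excluding rows of blocks where the
#' component is structurally undetermined — i.e. fluorescence-only blocks
#' for components with null fluorescence signal).
#'
#' @param fit Output of [fit_fusion_scenario()] (needs `model`, `ms`,
#'   `layout`).
#' @param scenario The matching [build_fusion_scenario()] output.
#' @return List with `perm` (model component matched to each truth
#'   constituent), `spectral_cosines`, `map_cosines` (both named by
#'   constituent role) and `truth_C` (the reference concentration matrix).
#' @export
evaluate_recovery <- function(fit, scenario) {
  truth <- scenario$truth
  model <- fit$model; ms <- fit$ms
  S_truth <- cbind(truth$spectra_fluor, truth$spectra_raman)
  n <- nrow(S_truth)
  mt <- match_components(S_truth, model$S_t)
  perm <- mt$perm
  roles <- truth$spec$components$role
  fb <- fit$layout$fluor_bin; cbn <- fit$layout$core_bin
  sub <- fit$layout$subregion
  truth_C <- matrix(0, nrow(ms$values), n)
  det_ok <- matrix(TRUE, nrow(ms$values), n)
  und <- model$undetermined
  for (k in seq_along(ms$row_blocks)) {
    b <- ms$row_blocks[[k]]
    if (grepl("^fluo_cell", b$id)) {
      cell <- as.integer(sub("fluo_cell", "", b$id))
      truth_C[b$rows, ] <- .maps_to_C(.bin_maps(truth$maps[[cell]], fb))
    } else if (grepl("^core_", b$id)) {
      nm <- sub("core_", "", b$id)
      reg <- truth$regions[[nm]]
      mm <- truth$maps[[reg$cell]][reg$actual[1]:(reg$actual[1] + sub - 1L),
                                   reg$actual[2]:(reg$actual[2] + sub - 1L), ,
                                   drop = FALSE]
      truth_C[b$rows, ] <- .maps_to_C(.bin_maps(mm, cbn))
    } else {
      nm <- sub("raman_", "", b$id)
      reg <- truth$regions[[nm]]
      truth_C[b$rows, ] <- .maps_to_C(
        truth$maps[[reg$cell]][reg$actual[1]:(reg$actual[1] + sub - 1L),
                               reg$actual[2]:(reg$actual[2] + sub - 1L), ,
                               drop = FALSE])
    }
    if (!is.null(und))
      det_ok[b$rows, which(und[k, perm])] <- FALSE
  }
  spectral <- mt$cosines
  map_cos <- vapply(seq_len(n), function(comp) {
    rows <- which(det_ok[, comp])
    a <- truth_C[rows, comp]; b <- model$C[rows, perm[comp]]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, 0)
  names(spectral) <- names(map_cos) <- roles
  list(perm = perm, spectral_cosines = spectral, map_cosines = map_cos,
       truth_C = truth_C)
}
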