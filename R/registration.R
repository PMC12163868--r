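#' Rigid transform between two images
#'
#' A shift plus in-plane rotation relating a moving image to a reference.
#' Positive `theta_deg` rotates counterclockwise (as displayed, row 1 at the
#' top) about the image centre; shifts are in pixels along (row, col).
#' The convention is `moving ~ apply_rigid_transform(ref, t)`: the transform
#' describes where the moving image sits relative to the reference, so
#' aligning the moving image back onto the reference grid uses
#' [invert_rigid_transform()].
#'
#' @param d_row,d_col Pixel shifts (may be fractional).
#' @param theta_deg Rotation in degrees, counterclockwise.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(d_row = 0, d_col = 0, theta_deg = 0) {
  structure(list(d_row = d_row, d_col = d_col, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> shift (%.3g, %.3g) px, rotation %.3g deg\n",
              x$d_row, x$d_col, x$theta_deg))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform].
#' @return The [rigid_transform] whose application undoes `t`.
#' @export
invert_rigid_transform <- function(t) {
  th <- -t$theta_deg * pi / 180
  # forward map: q = R(p - c) + c + d  =>  inverse shift is -R^{-1} d
  dr <- -(cos(th) * t$d_row + sin(th) * t$d_col)
  dc <- -(-sin(th) * t$d_row + cos(th) * t$d_col)
  rigid_transform(dr, dc, -t$theta_deg)
}

#' Crop a cube to a rectangular region
#'
#' @param cube An [hsi_cube].
#' @param top,left 1-based row/column of the upper-left corner.
#' @param height,width Region size in pixels.
#' @return Cropped [hsi_cube]; spectral axis and pixel size unchanged.
#' @export
crop_to_region <- function(cube, top, left, height, width) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  if (top < 1 || left < 1 || height < 1 || width < 1 ||
      top + height - 1 > d[1L] || left + width - 1 > d[2L])
    stop("crop region (", top, ",", left, ",", height, ",", width,
         ") outside cube bounds ", d[1L], "x", d[2L])
  hsi_cube(cube$data[top:(top + height - 1L), left:(left + width - 1L), ,
                     drop = FALSE],
           cube$spectral_axis, cube$axis_unit, cube$pixel_size, cube$modality)
}

# Warp a single 2-D matrix by a rigid transform (inverse bilinear mapping).
# Returns list(values, valid): valid is FALSE where the source location fell
# outside the image. Integer shifts with theta = 0 are exact relocations.
.warp_matrix <- function(m, t, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- t$theta_deg * pi / 180
  q <- cbind(rep(seq_len(nr), times = nc) - cr - t$d_row,
             rep(seq_len(nc), each = nr) - cc - t$d_col)
  # p = R^{-1} q + c ; R(theta) rotates (row, col) counterclockwise on screen
  pr <- cos(th) * q[, 1] + sin(th) * q[, 2] + cr
  pc <- -sin(th) * q[, 1] + cos(th) * q[, 2] + cc
  r0 <- floor(pr); c0 <- floor(pc)
  fr <- pr - r0; fc <- pc - c0
  valid <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
  g <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  v <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
    fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
  v[!valid] <- fill
  list(values = matrix(v, nr, nc), valid = matrix(valid, nr, nc))
}

#' Apply a rigid transform to a cube
#'
#' Rotates about the image centre then shifts, with bilinear interpolation
#' applied per spectral channel. Output pixels whose source location falls
#' outside the input take the `fill` value and are flagged invalid in the
#' `"valid"` attribute (a logical rows x cols matrix), so downstream fusion
#' can drop rows containing invalid pixels.
#'
#' @param cube An [hsi_cube] (a plain matrix is treated as a single-channel
#'   image and returned as a matrix).
#' @param t A [rigid_transform].
#' @param fill Fill value for out-of-source pixels.
#' @return Transformed [hsi_cube] (or matrix) with attribute `"valid"`.
#' @export
apply_rigid_transform <- function(cube, t, fill = 0) {
  if (is.matrix(cube)) {
    w <- .warp_matrix(cube, t, fill)
    out <- w$values
    attr(out, "valid") <- w$valid
    return(out)
  }
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  out <- array(0, d)
  valid <- NULL
  for (k in seq_len(d[3L])) {
    w <- .warp_matrix(cube$data[, , k], t, fill)
    out[, , k] <- w$values
    valid <- w$valid
  }
  res <- hsi_cube(out, cube$spectral_axis, cube$axis_unit, cube$pixel_size,
                  cube$modality)
  attr(res, "valid") <- valid
  res
}

#' Estimate the rigid transform between two distribution maps
#'
#' Exhaustive search over integer shifts within `shift_bound` and rotations
#' in `[-theta_bound, theta_bound]` on a `theta_step` grid, maximizing the
#' normalized cross-correlation between the reference map and the moving map
#' brought back by the candidate transform, evaluated on the overlapping
#' support only. Ties are broken by the smallest shift magnitude, then the
#' smallest absolute rotation. The returned transform satisfies
#' `moving ~ apply_rigid_transform(ref, t)`.
#'
#' @param ref_map,moving_map Numeric matrices of identical shape,
#'   non-constant (e.g. distribution maps of a constituent with a distinct
#'   spatial pattern, such as lipid droplets, from per-modality unmixing).
#' @param shift_bound Maximum absolute shift searched, in pixels.
#' @param theta_bound Maximum absolute rotation searched, degrees.
#' @param theta_step Rotation grid step, degrees.
#' @return List with `transform` (a [rigid_transform]) and `score` (the best
#'   normalized cross-correlation).
#' @export
estimate_rigid_transform <- function(ref_map, moving_map, shift_bound = 10L,
                                     theta_bound = 10, theta_step = 0.5) {
  stopifnot(is.matrix(ref_map), is.matrix(moving_map),
            all(dim(ref_map) == dim(moving_map)))
  if (stats::sd(ref_map) == 0 || stats::sd(moving_map) == 0)
    stop("correlation undefined: constant map")
  thetas <- if (theta_bound > 0) {
    th <- seq(0, theta_bound, by = theta_step)
    unique(c(0, as.vector(rbind(th[-1], -th[-1]))))  # 0 first, then by |theta|
  } else 0
  sb <- as.integer(shift_bound)
  shifts <- expand.grid(dr = -sb:sb, dc = -sb:sb)
  shifts <- shifts[order(shifts$dr^2 + shifts$dc^2), , drop = FALSE]
  nr <- nrow(ref_map); nc <- ncol(ref_map)
  best <- list(score = -Inf, t = rigid_transform())
  for (th in thetas) {
    # candidate transform (d, th): moving ~ translate(rotate(ref, th), d),
    # so undo the rotation on the moving map once, then scan translations
    w <- .warp_matrix(moving_map, rigid_transform(0, 0, -th))
    mv <- w$values; ok <- w$valid
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]; dc <- shifts$dc[s]
      r1 <- max(1L, 1L + dr); r2 <- min(nr, nr + dr)
      c1 <- max(1L, 1L + dc); c2 <- min(nc, nc + dc)
      if (r2 - r1 < 2L || c2 - c1 < 2L) next
      a <- ref_map[r1:r2 - dr, c1:c2 - dc, drop = FALSE]
      b <- mv[r1:r2, c1:c2, drop = FALSE]
      v <- ok[r1:r2, c1:c2]
      if (sum(v) < 9L) next
      av <- a[v]; bv <- b[v]
      if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
      sc <- stats::cor(av, bv)
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, t = rigid_transform(dr, dc, th))
      }
    }
  }
  if (!is.finite(best$score)) stop("no valid overlap found within the search bounds")
  list(transform = best$t, score = best$score)
}

#' Concatenate co-registered unfolded images column-wise
#'
#' Builds the row-wise augmented multiset of the fused core: the pixel
#' spectra of images sharing the same pixels (common scanned area and pixel
#' size) are concatenated along the spectral dimension. No values are
#' resampled; column-block boundaries are recorded.
#'
#' @param blocks Named list of unfolded matrices (pixels x channels), all
#'   with the same row count and pixel correspondence; names are used as
#'   block modalities.
#' @param spectral_axes Optional list of spectral axes, parallel to `blocks`.
#' @return List with `values` (the fused matrix) and `col_blocks`
#'   (descriptors with `id`, `cols`, `modality`, `spectral_axis`).
#' @export
fuse_rowwise <- function(blocks, spectral_axes = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  blocks <- lapply(blocks, as.matrix)
  nr <- vapply(blocks, nrow, 0L)
  if (length(unique(nr)) != 1L)
    stop("pixel-count mismatch across blocks: ", paste(nr, collapse = ", "))
  ids <- names(blocks) %||% paste0("block", seq_along(blocks))
  off <- 0L
  col_blocks <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    w <- ncol(blocks[[i]])
    col_blocks[[i]] <- list(id = ids[i], cols = (off + 1L):(off + w),
                            modality = ids[i],
                            spectral_axis = if (!is.null(spectral_axes))
                              spectral_axes[[i]] else seq_len(w))
    off <- off + w
  }
  list(values = do.call(cbind, blocks), col_blocks = col_blocks)
}
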