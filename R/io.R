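.provenance <- function(seed = NULL) {
  p <- list(tool = "mcrfuse",
            version = as.character(utils::packageVersion("mcrfuse")))
  if (!is.null(seed)) p$seed <- seed
  p
}

#' Write a hyperspectral cube to disk
#'
#' Two plain formats are supported. `"tiff"`: a multi-page TIFF (one page
#' per spectral channel, 32-bit float, values affinely rescaled to `[0, 1]`
#' with the scale and offset recorded in the sidecar; round-trip precision
#' is single-float). `"csv"`: the unfolded pixels x channels matrix as CSV
#' (full double precision). Either way a JSON sidecar `<path>.json` carries
#' the spectral axis, axis unit, pixel size, modality, image shape and a
#' provenance stamp.
#'
#' @param cube An [hsi_cube].
#' @param path Output path; extension `.tif`/`.tiff` or `.csv` selects the
#'   format unless `format` is given.
#' @param format `"tiff"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  meta <- list(shape = dim(cube$data), spectral_axis = cube$spectral_axis,
               axis_unit = cube$axis_unit, pixel_size = cube$pixel_size,
               modality = cube$modality, format = format,
               provenance = .provenance())
  if (format == "tiff") {
    lo <- min(cube$data); hi <- max(cube$data)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(cube$data)[3]), function(k)
      (cube$data[, , k] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta$value_offset <- lo
    meta$value_scale <- scale
  } else {
    utils::write.table(unfold(cube), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a hyperspectral cube written by [write_cube()]
#'
#' @param path Path to the `.tif`/`.csv` file; the `<path>.json` sidecar
#'   must sit next to it.
#' @return An [hsi_cube].
#' @export
read_cube <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar file ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (identical(meta$format, "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != shape[3])
      stop("TIFF has ", length(pages), " pages but sidecar declares ",
           shape[3], " channels")
    arr <- array(0, shape)
    for (k in seq_along(pages))
      arr[, , k] <- pages[[k]] * meta$value_scale + meta$value_offset
  } else {
    m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    if (ncol(m) != shape[3] || nrow(m) != shape[1] * shape[2])
      stop("CSV size ", nrow(m), "x", ncol(m),
           " inconsistent with sidecar shape ", paste(shape, collapse = "x"))
    arr <- refold(m, shape[1:2])
  }
  if (length(meta$spectral_axis) != shape[3])
    stop("sidecar spectral axis length does not match the channel count")
  hsi_cube(arr, meta$spectral_axis, meta$axis_unit, meta$pixel_size,
           meta$modality)
}

#' Write a multiset to a directory
#'
#' The container is a directory holding `manifest.json` (block layout,
#' presence table, spectral axes, provenance) plus one CSV file per observed
#' (row block, column block) cell. Missing cells are simply absent from
#' disk — masked entries are never stored as numbers.
#'
#' @param ms A [multiset_matrix].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiset <- function(ms, dir) {
  stopifnot(inherits(ms, "multiset_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(b) lapply(b, function(x) if (is.null(x)) NA else x)
  manifest <- list(
    n_rows = nrow(ms$values), n_cols = ncol(ms$values),
    row_blocks = lapply(ms$row_blocks, function(b)
      list(id = b$id, rows = range(b$rows), source = b$source %||% NA,
           shape = b$shape %||% NA)),
    col_blocks = lapply(ms$col_blocks, function(b)
      list(id = b$id, cols = range(b$cols), modality = b$modality %||% NA,
           spectral_axis = b$spectral_axis %||% NA)),
    presence = ms$presence,
    provenance = .provenance())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(ms$row_blocks)) for (l in seq_along(ms$col_blocks)) {
    if (!ms$presence[k, l]) next
    f <- file.path(dir, sprintf("block_%s_%s.csv", ms$row_blocks[[k]]$id,
                                ms$col_blocks[[l]]$id))
    utils::write.table(ms$values[ms$row_blocks[[k]]$rows,
                                 ms$col_blocks[[l]]$cols, drop = FALSE],
                       f, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a multiset directory written by [write_multiset()]
#'
#' @param dir The container directory.
#' @return A [multiset_matrix].
#' @export
read_multiset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a multiset container: missing ", mf)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rb <- lapply(seq_len(nrow(man$row_blocks)), function(k) {
    b <- man$row_blocks[k, ]
    list(id = b$id, rows = b$rows[[1]][1]:b$rows[[1]][2],
         source = b$source,
         shape = if (all(is.na(b$shape[[1]]))) NULL else as.integer(b$shape[[1]]))
  })
  cb <- lapply(seq_len(nrow(man$col_blocks)), function(l) {
    b <- man$col_blocks[l, ]
    list(id = b$id, cols = b$cols[[1]][1]:b$cols[[1]][2],
         modality = b$modality, spectral_axis = b$spectral_axis[[1]])
  })
  presence <- matrix(as.logical(man$presence), length(rb), length(cb))
  values <- matrix(0, man$n_rows, man$n_cols)
  for (k in seq_along(rb)) for (l in seq_along(cb)) {
    if (!presence[k, l]) next
    f <- file.path(dir, sprintf("block_%s_%s.csv", rb[[k]]$id, cb[[l]]$id))
    if (!file.exists(f))
      stop("manifest declares block (", rb[[k]]$id, ", ", cb[[l]]$id,
           ") observed but ", basename(f), " is missing")
    m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    if (nrow(m) != length(rb[[k]]$rows) || ncol(m) != length(cb[[l]]$cols))
      stop("block file ", basename(f), " has size ", nrow(m), "x", ncol(m),
           " but the manifest implies ", length(rb[[k]]$rows), "x",
           length(cb[[l]]$cols))
    values[rb[[k]]$rows, cb[[l]]$cols] <- m
  }
  multiset_matrix(values, rb, cb, observed = presence)
}
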