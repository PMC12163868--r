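#' Assemble an incomplete multiset from a fused core and extra blocks
#'
#' Builds the single augmented data matrix of an image-fusion scenario in
#' which modalities differ in scanned area and pixel size: the fused core
#' (pixels measured by every modality, channels concatenated) sits in the
#' middle; images measured by the first modality only are appended on top
#' and images measured by the other modalities at the bottom, each facing a
#' missing block in the complementary channels. Missingness is recorded in
#' the observed mask, never imputed.
#'
#' @param fused_core List as returned by [fuse_rowwise()]: `values` and
#'   `col_blocks`; may also carry `row_blocks` (descriptors partitioning the
#'   core rows, e.g. one per fused subregion) used for block-level
#'   constraints.
#' @param extra_blocks List of modality-specific blocks, each a list with
#'   `values` (unfolded matrix), `modality` (must match one core column
#'   block), and optionally `id`, `source`, `shape`.
#' @return A [multiset_matrix]. Row-block ids are taken from the blocks;
#'   core row blocks keep their ids (default `"core"`).
#' @export
assemble_incomplete_multiset <- function(fused_core, extra_blocks = list()) {
  cb <- fused_core$col_blocks
  mods <- vapply(cb, function(b) b$modality, "")
  widths <- vapply(cb, function(b) length(b$cols), 0L)
  for (b in extra_blocks) {
    l <- match(b$modality, mods)
    if (is.na(l))
      stop("extra block modality '", b$modality,
           "' does not match any core column block (",
           paste(mods, collapse = ", "), ")")
    if (ncol(b$values) != widths[l])
      stop("extra block '", b$id %||% b$modality, "' has ", ncol(b$values),
           " channels but the '", b$modality, "' column block has ", widths[l])
  }
  top <- Filter(function(b) match(b$modality, mods) == 1L, extra_blocks)
  bottom <- Filter(function(b) match(b$modality, mods) > 1L, extra_blocks)
  core_rb <- fused_core$row_blocks %||%
    list(list(id = "core", rows = seq_len(nrow(fused_core$values))))

  nall <- ncol(fused_core$values)
  expand_rows <- function(b) {
    l <- match(b$modality, mods)
    v <- matrix(0, nrow(b$values), nall)
    v[, cb[[l]]$cols] <- b$values
    v
  }
  pieces <- c(lapply(top, expand_rows), list(fused_core$values),
              lapply(bottom, expand_rows))
  values <- do.call(rbind, pieces)

  row_blocks <- list()
  presence <- NULL
  off <- 0L
  add_block <- function(id, nrows, source, shape, obs_row) {
    row_blocks[[length(row_blocks) + 1L]] <<-
      list(id = id, rows = (off + 1L):(off + nrows), source = source,
           shape = shape)
    presence <<- rbind(presence, obs_row)
    off <<- off + nrows
  }
  for (b in top)
    add_block(b$id %||% paste0("top", length(row_blocks) + 1L), nrow(b$values),
              b$source %||% NA, b$shape %||% NULL, mods == b$modality)
  for (rb in core_rb) {
    nrows <- length(rb$rows)
    add_block(rb$id %||% "core", nrows, rb$source %||% NA, rb$shape %||% NULL,
              rep(TRUE, length(mods)))
  }
  for (b in bottom)
    add_block(b$id %||% paste0("bot", length(row_blocks) + 1L), nrow(b$values),
              b$source %||% NA, b$shape %||% NULL, mods == b$modality)

  multiset_matrix(values, row_blocks, cb, observed = presence)
}

# per-row-block masked solve of C given S_t; returns C plus an undetermined
# flag matrix (row block x component) marking components with no observed
# signal in a block's observed channels
.step_C_missing <- function(ms, S_t, allowC = NULL, nonneg = FALSE) {
  n <- nrow(S_t)
  if (is.null(allowC)) allowC <- rep(list(seq_len(n)), length(ms$row_blocks))
  C <- matrix(0, nrow(ms$values), n)
  und <- matrix(FALSE, length(ms$row_blocks), n,
                dimnames = list(vapply(ms$row_blocks, function(b) b$id, ""),
                                NULL))
  for (k in seq_along(ms$row_blocks)) {
    rows <- ms$row_blocks[[k]]$rows
    obs <- unlist(lapply(which(ms$presence[k, ]),
                         function(l) ms$col_blocks[[l]]$cols))
    a <- allowC[[k]]
    Sk <- S_t[a, obs, drop = FALSE]
    # components with no signal in the observed channels of this block are
    # structurally unidentifiable here: coefficients set to 0 and flagged
    alive <- rowSums(Sk^2) > 1e-24 * max(rowSums(S_t^2))
    und[k, a[!alive]] <- TRUE
    a <- a[alive]
    if (!length(a)) stop("row block '", ms$row_blocks[[k]]$id,
                         "': no component has observed signal")
    Sk <- Sk[alive, , drop = FALSE]
    AtA <- tcrossprod(Sk)
    AtB <- Sk %*% t(ms$values[rows, obs, drop = FALSE])
    X <- tryCatch(
      if (nonneg) nnls_multi(AtA, AtB)
      else .solve_sym(AtA, AtB, "observed spectral cross-product"),
      error = function(e)
        stop("row block '", ms$row_blocks[[k]]$id, "': components ",
             paste(a, collapse = ", "), " are not separable from its observed channels (",
             conditionMessage(e), ")", call. = FALSE))
    C[rows, a] <- t(X)
  }
  list(C = C, undetermined = und)
}

.step_S_missing <- function(ms, C, allowS = NULL, nonneg = FALSE) {
  n <- ncol(C)
  if (is.null(allowS)) allowS <- rep(list(seq_len(n)), length(ms$col_blocks))
  S_t <- matrix(0, n, ncol(ms$values))
  for (l in seq_along(ms$col_blocks)) {
    cols <- ms$col_blocks[[l]]$cols
    obs <- unlist(lapply(which(ms$presence[, l]),
                         function(k) ms$row_blocks[[k]]$rows))
    a <- allowS[[l]]
    Ck <- C[obs, a, drop = FALSE]
    alive <- colSums(Ck^2) > 1e-24 * max(colSums(C^2), .Machine$double.xmin)
    a <- a[alive]
    if (!length(a)) stop("column block '", ms$col_blocks[[l]]$id,
                         "': no component has nonzero concentration in its observed rows")
    Ck <- Ck[, alive, drop = FALSE]
    AtA <- crossprod(Ck)
    AtB <- crossprod(Ck, ms$values[obs, cols, drop = FALSE])
    X <- tryCatch(
      if (nonneg) nnls_multi(AtA, AtB)
      else .solve_sym(AtA, AtB, "observed concentration cross-product"),
      error = function(e)
        stop("column block '", ms$col_blocks[[l]]$id, "': components ",
             paste(a, collapse = ", "), " are not separable from its observed rows (",
             conditionMessage(e), ")", call. = FALSE))
    S_t[a, cols] <- X
  }
  S_t
}

#' Missing-data-aware update of the concentration matrix
#'
#' For each row i of the multiset, `c(i,:)` is the least-squares solution of
#' the observed entries of that row against the corresponding columns of the
#' spectra: `c(i,:) = d(i, obs) S_obs (t(S_obs) S_obs)^{-1}`. Rows sharing an
#' observation pattern (block-wise missingness guarantees only a few
#' patterns) share one factorization; the result equals the per-row
#' definition. With a fully observed mask this reduces exactly to
#' [update_C()]. Components with no signal in a row block's observed
#' channels are structurally unidentifiable from that block: their
#' coefficients are set to zero and flagged in the `"undetermined"`
#' attribute (constrain them to zero explicitly, or accept the flag).
#'
#' @param ms A [multiset_matrix].
#' @param S_t Spectral matrix (components x total channels).
#' @return Concentration matrix with attribute `"undetermined"` (logical,
#'   row blocks x components).
#' @export
update_C_missing <- function(ms, S_t) {
  stopifnot(inherits(ms, "multiset_matrix"))
  r <- .step_C_missing(ms, S_t)
  out <- r$C
  attr(out, "undetermined") <- r$undetermined
  out
}

#' Missing-data-aware update of the spectral matrix
#'
#' For each column j, `s(:,j)` is the least-squares solution using the
#' non-missing rows of that column: `s(:,j) = (t(C_obs) C_obs)^{-1} t(C_obs)
#' d(obs, j)`. Columns within one column block share an observation pattern
#' and are solved jointly; with a fully observed mask this reduces exactly
#' to [update_S()].
#'
#' @param ms A [multiset_matrix].
#' @param C Concentration matrix (total pixels x components).
#' @return Spectral matrix (components x total channels).
#' @export
update_S_missing <- function(ms, C) {
  stopifnot(inherits(ms, "multiset_matrix"))
  .step_S_missing(ms, C)
}

#' Run MCR-ALS on an incomplete multiset
#'
#' Alternating least squares over the observed entries only: the
#' concentration and spectral updates are computed row-block by row-block
#' and column-block by column-block, restricted to the observed cells of the
#' presence table ([update_C_missing()], [update_S_missing()]), so no
#' imputation of missing blocks is ever performed. Constraints
#' (non-negativity, correspondence of species, equality-to-zero spectral
#' segments) are applied as in the complete case, and full `C` and `t(S)`
#' matrices are returned. Fit metrics are computed over observed entries,
#' overall and per row block; convergence is judged on the overall lack of
#' fit.
#'
#' @param ms A [multiset_matrix].
#' @param S0 Initial spectra spanning the full concatenated spectral space
#'   (components x total channels), e.g. combined per-modality pure spectra
#'   or [simplisma_initial_spectra()] on the fused core.
#' @param constraints A [constraint_set]; zero constraints reference the
#'   multiset's block ids.
#' @param convergence A [convergence_spec].
#' @return An [mcr_model] with per-row-block metrics in `block_metrics` and
#'   the structural-identifiability flags in `undetermined`.
#' @export
run_incomplete_mcr <- function(ms, S0, constraints = constraint_set(),
                               convergence = convergence_spec()) {
  stopifnot(inherits(ms, "multiset_matrix"))
  n <- nrow(S0)
  if (ncol(S0) != ncol(ms$values))
    stop("S0 must span the full concatenated spectral space (",
         ncol(ms$values), " channels)")
  allowC <- .allowed_C(constraints, ms$row_blocks, n)
  allowS <- .allowed_S(constraints, ms$col_blocks, n)
  nnC <- constraints$nonneg_C && constraints$nonneg_mode == "nnls"
  nnS <- constraints$nonneg_S && constraints$nonneg_mode == "nnls"
  mask <- ms$observed_mask
  ssd <- sum(ms$values[mask]^2)
  S_t <- S0
  hist <- list()
  lof_prev <- Inf
  converged <- FALSE; reason <- "max_iters reached"
  und <- NULL
  for (it in seq_len(convergence$max_iters)) {
    st <- .step_C_missing(ms, S_t, allowC, nonneg = nnC)
    C <- st$C; und <- st$undetermined
    if (constraints$nonneg_C && !nnC) C[C < 0] <- 0
    R <- ms$values - C %*% S_t
    sse_half <- sum(R[mask]^2)
    S_t <- .step_S_missing(ms, C, allowS, nonneg = nnS)
    if (constraints$nonneg_S && !nnS) S_t[S_t < 0] <- 0
    nm <- .normalize_model(C, S_t)
    C <- nm$C; S_t <- nm$S_t
    R <- ms$values - C %*% S_t
    sse <- sum(R[mask]^2)
    lof <- 100 * sqrt(sse / ssd)
    hist[[it]] <- data.frame(iter = it, lof_percent = lof,
                             variance_percent = 100 * (1 - sse / ssd),
                             ssq_after_C = sse_half, ssq_after_S = sse)
    if (is.finite(lof_prev)) {
      rel <- abs(lof_prev - lof) / max(lof, .Machine$double.eps) * 100
      if (rel < convergence$lof_change_tol) {
        converged <- TRUE
        reason <- sprintf("relative LOF change %.3g%% below tolerance %.3g%%",
                          rel, convergence$lof_change_tol)
        break
      }
    }
    lof_prev <- lof
  }
  E <- ms$values - C %*% S_t
  E[!mask] <- 0
  block_metrics <- lapply(ms$row_blocks, function(b) {
    fit_metrics(ms$values[b$rows, , drop = FALSE], E[b$rows, , drop = FALSE],
                mask[b$rows, , drop = FALSE])
  })
  names(block_metrics) <- vapply(ms$row_blocks, function(b) b$id, "")
  mcr_model(C, S_t, E, fit_metrics(ms, E), do.call(rbind, hist), converged,
            reason, block_metrics = block_metrics, undetermined = und)
}

#' Fill the missing blocks of a multiset from a fitted model
#'
#' Returns the data matrix with every masked (never measured) entry replaced
#' by the model's implied value `C %*% t(S)`; observed entries are returned
#' untouched. With non-negativity active on both factors, the filled values
#' are non-negative. This renders, e.g., the complementary-modality signal
#' over areas scanned by only one technique.
#'
#' @param model An [mcr_model] from [run_incomplete_mcr()].
#' @param ms The [multiset_matrix] the model was fitted to.
#' @return Numeric matrix the shape of `ms$values`.
#' @export
predict_missing_blocks <- function(model, ms) {
  stopifnot(inherits(model, "mcr_model"), inherits(ms, "multiset_matrix"))
  out <- ms$values
  hat <- model$C %*% model$S_t
  out[!ms$observed_mask] <- hat[!ms$observed_mask]
  out
}
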