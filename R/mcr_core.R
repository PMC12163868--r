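#' Constraint set for MCR-ALS
#'
#' Constraints applied to the concentration and spectral matrices during the
#' alternating least-squares optimization: non-negativity (clipping or true
#' non-negative least squares), correspondence of species (components forced
#' to zero concentration in row blocks where they are known absent) and
#' equality-to-zero spectral segments (components with null signal in a
#' modality, e.g. non-fluorescent constituents in fluorescence channels).
#'
#' @param nonneg_C,nonneg_S Apply non-negativity to C / to the spectra.
#' @param zero_C_blocks List of `c(row_block_id, component)` pairs: that
#'   component's concentration is zero throughout that row block.
#' @param zero_S_segments List of `c(component, col_block_id)` pairs: that
#'   component's spectrum is zero over that column block's channels.
#' @param nonneg_mode `"nnls"` (non-negative least squares, the
#'   least-squares-consistent interpretation, default) or `"clip"`
#'   (negatives set to zero after an unconstrained solve; faster).
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(nonneg_C = TRUE, nonneg_S = TRUE,
                           zero_C_blocks = list(), zero_S_segments = list(),
                           nonneg_mode = c("nnls", "clip")) {
  nonneg_mode <- match.arg(nonneg_mode)
  chk <- function(x, nm) {
    for (el in x) if (length(el) != 2L)
      stop(nm, " entries must be (block id, component) pairs")
    x
  }
  structure(list(nonneg_C = nonneg_C, nonneg_S = nonneg_S,
                 zero_C_blocks = chk(zero_C_blocks, "zero_C_blocks"),
                 zero_S_segments = chk(zero_S_segments, "zero_S_segments"),
                 nonneg_mode = nonneg_mode),
            class = "constraint_set")
}

#' Convergence settings for MCR-ALS
#'
#' The iteration stops when the relative change of the lack of fit between
#' consecutive iterations falls below `lof_change_tol` (in percent of the
#' current LOF) or after `max_iters` iterations.
#'
#' @param max_iters Maximum number of full ALS cycles (>= 1).
#' @param lof_change_tol Relative LOF change threshold in percent (>= 0).
#' @return Object of class `convergence_spec`.
#' @export
convergence_spec <- function(max_iters = 100L, lof_change_tol = 0.1) {
  stopifnot(max_iters >= 1, lof_change_tol >= 0)
  structure(list(max_iters = as.integer(max_iters),
                 lof_change_tol = lof_change_tol),
            class = "convergence_spec")
}

# symmetric positive-definite solve with a diagnostic on failure
.solve_sym <- function(A, B, context = "least-squares system") {
  ch <- try(chol(A), silent = TRUE)
  if (!inherits(ch, "try-error") && (nrow(A) == 1L || rcond(A) >= 1e-12))
    return(backsolve(ch, backsolve(ch, B, transpose = TRUE)))
  if (nrow(A) > 1L) {
    nrm <- sqrt(diag(A))
    cs <- abs(A / outer(nrm, nrm))
    diag(cs) <- 0
    pair <- which(cs > 1 - 1e-8, arr.ind = TRUE)
    if (nrow(pair))
      stop(context, " is singular: components ",
           paste(unique(pmin(pair[, 1], pair[, 2])), collapse = ", "),
           " are collinear with components ",
           paste(unique(pmax(pair[, 1], pair[, 2])), collapse = ", "))
  }
  stop(context, " is singular or rank-deficient")
}

#' Multi-column non-negative least squares
#'
#' Solves `min ||A x_j - b_j||` subject to `x_j >= 0` for many right-hand
#' sides simultaneously, given the normal-equation matrices `AtA = t(A) A`
#' and `AtB = t(A) B`, using block principal pivoting with grouped solves
#' over columns sharing a passive set. This is the workhorse behind the
#' `"nnls"` non-negativity mode.
#'
#' @param AtA p x p symmetric positive-definite matrix.
#' @param AtB p x m matrix of projected right-hand sides.
#' @param max_cycles Safety cap on pivoting cycles.
#' @return p x m non-negative solution matrix.
#' @export
nnls_multi <- function(AtA, AtB, max_cycles = 100L) {
  AtB <- as.matrix(AtB)
  p <- nrow(AtA); m <- ncol(AtB)
  Fs <- matrix(TRUE, p, m)       # passive (free) set, start unconstrained
  X <- .solve_sym(AtA, AtB, "non-negative least-squares system")
  Y <- matrix(0, p, m)
  alpha <- rep.int(3L, m); beta <- rep.int(p + 1L, m)
  tol <- 1e-12 * max(abs(AtB), 1)
  for (cycle in seq_len(max_cycles)) {
    V <- (Fs & (X < -tol)) | (!Fs & (Y < -tol))
    nv <- colSums(V)
    if (!any(nv > 0L)) break
    for (j in which(nv > 0L)) {
      if (nv[j] < beta[j]) {
        beta[j] <- nv[j]; alpha[j] <- 3L
        Fs[V[, j], j] <- !Fs[V[, j], j]
      } else if (alpha[j] >= 1L) {
        alpha[j] <- alpha[j] - 1L
        Fs[V[, j], j] <- !Fs[V[, j], j]
      } else {
        i <- max(which(V[, j]))
        Fs[i, j] <- !Fs[i, j]
      }
    }
    key <- apply(Fs, 2L, function(z) paste(which(z), collapse = ","))
    for (k in unique(key)) {
      cols <- which(key == k)
      idx <- Fs[, cols[1L]]
      X[, cols] <- 0
      if (any(idx))
        X[idx, cols] <- .solve_sym(AtA[idx, idx, drop = FALSE],
                                   AtB[idx, cols, drop = FALSE],
                                   "non-negative least-squares subsystem")
      Y[, cols] <- 0
      if (any(!idx)) {
        Yk <- -AtB[!idx, cols, drop = FALSE]
        if (any(idx))
          Yk <- Yk + AtA[!idx, idx, drop = FALSE] %*% X[idx, cols, drop = FALSE]
        Y[!idx, cols] <- Yk
      }
    }
  }
  X[X < 0] <- 0
  X
}

#' SIMPLISMA-style selection of initial spectra
#'
#' Selects the `n` "purest" rows of `D` as initial spectral estimates: the
#' purity of row i is `sd_i / (mean_i + alpha * max(mean))`, reweighted at
#' each step by a determinant-based independence factor computed from the
#' correlation-around-origin matrix of the scaled rows, so that each new
#' selection is maximally independent of the rows already chosen. The method
#' is deterministic.
#'
#' @param D Data matrix (rows are candidate pixel spectra).
#' @param n Number of components to select.
#' @param alpha Noise-correction fraction (> 0) applied as an offset on the
#'   mean in the purity denominator.
#' @return `n x ncol(D)` matrix of selected spectra, each scaled to unit
#'   Euclidean norm. The selected row indices are in attribute `"rows"`.
#' @export
simplisma_initial_spectra <- function(D, n, alpha = 0.05) {
  D <- as.matrix(D)
  if (n > min(dim(D))) stop("n exceeds the matrix dimensions")
  if (alpha <= 0) stop("alpha must be positive")
  mu <- rowMeans(D)
  sg <- sqrt(rowMeans(D^2) - mu^2)
  off <- alpha * max(mu)
  lam <- sqrt(mu^2 + (sg + off)^2)
  Z <- D / lam
  COO <- Z %*% t(Z) / ncol(D)
  purity0 <- sg / (mu + off)
  sel <- integer(0)
  for (k in seq_len(n)) {
    w <- vapply(seq_len(nrow(D)), function(i) {
      if (i %in% sel) return(-Inf)
      det(COO[c(sel, i), c(sel, i), drop = FALSE])
    }, 0)
    p <- w * purity0
    if (max(p, na.rm = TRUE) <= 1e-12 && k > 1L)
      stop("rank deficiency: no independent row left for component ", k)
    sel <- c(sel, which.max(p))
  }
  S0 <- D[sel, , drop = FALSE]
  S0 <- S0 / sqrt(rowSums(S0^2))
  attr(S0, "rows") <- sel
  S0
}

#' Least-squares update of the concentration matrix
#'
#' The unconstrained ALS half-step `C = D S (t(S) S)^{-1}`, minimizing
#' `||D - C t(S)||^2` for fixed spectra.
#'
#' @param D Data matrix (pixels x channels).
#' @param S_t Spectral matrix (components x channels).
#' @return Concentration matrix (pixels x components).
#' @export
update_C <- function(D, S_t) {
  AtA <- tcrossprod(S_t)
  t(.solve_sym(AtA, S_t %*% t(D), "spectral cross-product t(S) S"))
}

#' Least-squares update of the spectral matrix
#'
#' The unconstrained ALS half-step `t(S) = (t(C) C)^{-1} t(C) D`.
#'
#' @param D Data matrix (pixels x channels).
#' @param C Concentration matrix (pixels x components).
#' @return Spectral matrix (components x channels).
#' @export
update_S <- function(D, C) {
  AtA <- crossprod(C)
  .solve_sym(AtA, crossprod(C, D), "concentration cross-product t(C) C")
}

# expand (block id, component) pairs into a per-block list of zeroed
# components; ids may be given as block ids or 1-based block indices
.zero_map <- function(pairs, blocks) {
  ids <- vapply(blocks, function(b) as.character(b$id), "")
  out <- rep(list(integer(0)), length(blocks))
  for (el in pairs) {
    bid <- as.character(el[[1]]); comp <- as.integer(el[[2]])
    k <- match(bid, ids)
    if (is.na(k)) {
      k <- suppressWarnings(as.integer(bid))
      if (is.na(k) || k < 1L || k > length(blocks))
        stop("constraint references unknown block '", bid, "'")
    }
    out[[k]] <- union(out[[k]], comp)
  }
  out
}

#' Apply constraints to a concentration or spectral matrix
#'
#' Applies non-negativity (in `"clip"` mode negatives are set to zero; in
#' `"nnls"` mode, when `D` and the complementary matrix are supplied, the
#' affected rows/columns are re-solved by non-negative least squares), then
#' the equality-to-zero masks: zeroed (block, component) entries are exactly
#' zero afterwards. Masks are applied after non-negativity.
#'
#' @param M The matrix being constrained: `C` (pixels x components) when
#'   `side = "C"`, or `S_t` (components x channels) when `side = "S"`.
#' @param constraints A [constraint_set].
#' @param side `"C"` or `"S"`.
#' @param blocks Row-block descriptors (side `"C"`) or column-block
#'   descriptors (side `"S"`) used to resolve the zero masks; may be omitted
#'   when no zero constraints reference blocks.
#' @param D,other Optional data matrix and complementary factor (`S_t` for
#'   side `"C"`, `C` for side `"S"`) enabling the `"nnls"` re-solve.
#' @return Constrained matrix of the same shape.
#' @export
apply_constraints <- function(M, constraints, side = c("C", "S"),
                              blocks = NULL, D = NULL, other = NULL) {
  side <- match.arg(side)
  nonneg <- if (side == "C") constraints$nonneg_C else constraints$nonneg_S
  if (nonneg) {
    if (constraints$nonneg_mode == "nnls" && !is.null(D) && !is.null(other)) {
      if (side == "C") {
        M <- t(nnls_multi(tcrossprod(other), other %*% t(D)))
      } else {
        M <- nnls_multi(crossprod(other), crossprod(other, D))
      }
    } else {
      M[M < 0] <- 0
    }
  }
  pairs <- if (side == "C") constraints$zero_C_blocks else constraints$zero_S_segments
  if (length(pairs)) {
    if (is.null(blocks)) stop("zero constraints given but no block layout supplied")
    if (side == "C") {
      zm <- .zero_map(pairs, blocks)
      for (k in seq_along(blocks))
        if (length(zm[[k]])) M[blocks[[k]]$rows, zm[[k]]] <- 0
    } else {
      # zero_S_segments pairs are (component, col_block)
      swapped <- lapply(pairs, function(el) c(el[[2]], el[[1]]))
      zm <- .zero_map(swapped, blocks)
      for (l in seq_along(blocks))
        if (length(zm[[l]])) M[zm[[l]], blocks[[l]]$cols] <- 0
    }
  }
  M
}

# scale each component spectrum to unit Euclidean norm over the full
# (augmented) spectrum, absorbing the inverse factor into C; C %*% S_t is
# unchanged. Errors if a component has collapsed to an all-zero spectrum.
.normalize_model <- function(C, S_t) {
  nrm <- sqrt(rowSums(S_t^2))
  if (any(nrm <= 0))
    stop("component ", paste(which(nrm <= 0), collapse = ", "),
         " collapsed to a zero spectrum")
  list(C = C * rep(nrm, each = nrow(C)), S_t = S_t / nrm)
}

# allowed components per row block given correspondence-of-species zeros
.allowed_C <- function(constraints, row_blocks, n) {
  zm <- .zero_map(constraints$zero_C_blocks, row_blocks)
  lapply(zm, function(z) setdiff(seq_len(n), z))
}

.allowed_S <- function(constraints, col_blocks, n) {
  swapped <- lapply(constraints$zero_S_segments, function(el) c(el[[2]], el[[1]]))
  zm <- .zero_map(swapped, col_blocks)
  allowed <- lapply(zm, function(z) setdiff(seq_len(n), z))
  dropped <- setdiff(seq_len(n), unique(unlist(allowed)))
  if (length(dropped))
    stop("component ", paste(dropped, collapse = ", "),
         " is zeroed in every column block")
  allowed
}

#' Run complete-data MCR-ALS
#'
#' Alternates the least-squares updates of `C` and `t(S)` under the given
#' constraints until the relative change in lack of fit falls below the
#' tolerance or the iteration cap is reached. After each spectral update,
#' every component spectrum is scaled to unit Euclidean norm with the
#' inverse factor absorbed into `C`, which leaves the reconstruction
#' `C %*% S_t` unchanged. Works for single unfolded images and for complete
#' row- and/or column-wise augmented multisets (supply block layouts when
#' block-level constraints are used).
#'
#' @param D Data matrix (pixels x channels), e.g. from [unfold()] or
#'   [fuse_rowwise()].
#' @param S0 Initial spectra (components x channels), e.g. from
#'   [simplisma_initial_spectra()]. Exactly one of `S0`/`C0` must be given.
#' @param C0 Initial concentrations (pixels x components).
#' @param constraints A [constraint_set].
#' @param convergence A [convergence_spec].
#' @param row_blocks,col_blocks Optional block descriptors (see
#'   [multiset_matrix]) required when zero constraints reference blocks.
#' @return An [mcr_model].
#' @export
run_mcr_als <- function(D, S0 = NULL, C0 = NULL,
                        constraints = constraint_set(),
                        convergence = convergence_spec(),
                        row_blocks = NULL, col_blocks = NULL) {
  D <- as.matrix(D)
  if (is.null(S0) == is.null(C0))
    stop("exactly one of S0 or C0 must be supplied")
  n <- if (!is.null(S0)) nrow(S0) else ncol(C0)
  if (is.null(row_blocks)) row_blocks <- list(list(id = "r1", rows = seq_len(nrow(D))))
  if (is.null(col_blocks)) col_blocks <- list(list(id = "c1", cols = seq_len(ncol(D))))
  allowC <- .allowed_C(constraints, row_blocks, n)
  allowS <- .allowed_S(constraints, col_blocks, n)
  S_t <- S0
  if (!is.null(C0)) {
    C <- C0
    S_t <- .step_S_dense(D, C, constraints, col_blocks, allowS)
    nm <- .normalize_model(C, S_t)
    C <- nm$C; S_t <- nm$S_t
  }
  ssd <- sum(D^2)
  hist <- list()
  lof_prev <- Inf
  converged <- FALSE; reason <- "max_iters reached"
  for (it in seq_len(convergence$max_iters)) {
    C <- .step_C_dense(D, S_t, constraints, row_blocks, allowC)
    sse_half <- sum((D - C %*% S_t)^2)
    S_t <- .step_S_dense(D, C, constraints, col_blocks, allowS)
    nm <- .normalize_model(C, S_t)
    C <- nm$C; S_t <- nm$S_t
    sse <- sum((D - C %*% S_t)^2)
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
        lof_prev <- lof
        break
      }
    }
    lof_prev <- lof
  }
  E <- D - C %*% S_t
  mcr_model(C, S_t, E, fit_metrics(D, E), do.call(rbind, hist),
            converged, reason)
}

# dense C half-step with constraints; per-row-block restricted solves when
# correspondence-of-species zeros are active
.step_C_dense <- function(D, S_t, constraints, row_blocks, allowC) {
  n <- nrow(S_t)
  use_nnls <- constraints$nonneg_C && constraints$nonneg_mode == "nnls"
  C <- matrix(0, nrow(D), n)
  full <- all(vapply(allowC, length, 0L) == n)
  if (full) {
    AtA <- tcrossprod(S_t)
    AtB <- S_t %*% t(D)
    X <- if (use_nnls) nnls_multi(AtA, AtB)
         else .solve_sym(AtA, AtB, "spectral cross-product t(S) S")
    C <- t(X)
  } else {
    for (k in seq_along(row_blocks)) {
      a <- allowC[[k]]
      rows <- row_blocks[[k]]$rows
      Sk <- S_t[a, , drop = FALSE]
      AtA <- tcrossprod(Sk)
      AtB <- Sk %*% t(D[rows, , drop = FALSE])
      X <- if (use_nnls) nnls_multi(AtA, AtB)
           else .solve_sym(AtA, AtB, "spectral cross-product t(S) S")
      C[rows, a] <- t(X)
    }
  }
  if (constraints$nonneg_C && !use_nnls) C[C < 0] <- 0
  C
}

.step_S_dense <- function(D, C, constraints, col_blocks, allowS) {
  n <- ncol(C)
  use_nnls <- constraints$nonneg_S && constraints$nonneg_mode == "nnls"
  S_t <- matrix(0, n, ncol(D))
  full <- all(vapply(allowS, length, 0L) == n)
  if (full) {
    AtA <- crossprod(C)
    AtB <- crossprod(C, D)
    S_t <- if (use_nnls) nnls_multi(AtA, AtB)
           else .solve_sym(AtA, AtB, "concentration cross-product t(C) C")
  } else {
    for (l in seq_along(col_blocks)) {
      a <- allowS[[l]]
      cols <- col_blocks[[l]]$cols
      Ck <- C[, a, drop = FALSE]
      AtA <- crossprod(Ck)
      AtB <- crossprod(Ck, D[, cols, drop = FALSE])
      X <- if (use_nnls) nnls_multi(AtA, AtB)
           else .solve_sym(AtA, AtB, "concentration cross-product t(C) C")
      S_t[a, cols] <- X
    }
  }
  if (constraints$nonneg_S && !use_nnls) S_t[S_t < 0] <- 0
  S_t
}

#' Cosine similarity between matched components
#'
#' Cosine of the angle between corresponding rows (or columns) of two
#' matrices, after optimal one-to-one matching that maximizes the total
#' cosine similarity. The assignment is solved exactly by exhaustive
#' permutation search (components are few).
#'
#' @param A,B Matrices with components in rows (e.g. two spectral matrices,
#'   or transposed concentration matrices).
#' @return List with `perm` (indices into rows of `B` matched to rows of
#'   `A`), `cosines` (per matched pair) and `mean_cosine`.
#' @export
match_components <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  n <- nrow(A)
  if (n > 8L) stop("exhaustive matching supported for up to 8 components")
  nA <- sqrt(rowSums(A^2)); nB <- sqrt(rowSums(B^2))
  S <- (A %*% t(B)) / outer(pmax(nA, 1e-300), pmax(nB, 1e-300))
  perms <- .permutations(n)
  tot <- apply(perms, 1L, function(p) sum(S[cbind(seq_len(n), p)]))
  best <- unname(perms[which.max(tot), ])
  cosines <- S[cbind(seq_len(n), best)]
  list(perm = best, cosines = cosines, mean_cosine = mean(cosines))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' SVD scree of a data matrix
#'
#' Singular values and the cumulative explained variance they carry, as
#' guidance for choosing the number of components.
#'
#' @param D Data matrix.
#' @param k Number of leading singular values reported.
#' @return Data frame with `component`, `singular_value`,
#'   `variance_percent`, `cumulative_percent`.
#' @export
svd_scree <- function(D, k = 10L) {
  d <- svd(as.matrix(D), nu = 0, nv = 0)$d
  k <- min(k, length(d))
  v <- d^2 / sum(d^2) * 100
  data.frame(component = seq_len(k), singular_value = d[seq_len(k)],
             variance_percent = v[seq_len(k)],
             cumulative_percent = cumsum(v)[seq_len(k)])
}
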