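#' Reference singular vectors for adaptive weighting
#'
#' Computes the first left and right singular vectors of the
#' cross-correlation matrix `K`.  These serve as the adaptive reference
#' weights: during soft-thresholding, coefficient j of `u` is penalized by
#' `lambda_u / |u_svd[j]|^gamma`, so directions the unpenalized solution
#' deems weak are shrunk harder (adaptive-lasso logic).
#'
#' Sign convention: both vectors are flipped together so that the
#' largest-magnitude entry of the left vector is positive, removing the
#' sign ambiguity of the SVD.
#'
#' @param K numeric p x q cross-correlation matrix (see
#'   [cross_correlation()]).
#' @return A list with unit-norm numeric vectors `u_svd` (length p) and
#'   `v_svd` (length q).
#' @export
svd_reference_vectors <- function(K) {
  K <- as.matrix(K)
  if (anyNA(K)) stop("K contains NA entries")
  if (all(K == 0)) stop("K is identically zero; no singular structure")
  sv <- svd(K, nu = 1L, nv = 1L)
  u <- drop(sv$u)
  v <- drop(sv$v)
  if (u[which.max(abs(u))] < 0) {
    u <- -u
    v <- -v
  }
  list(u_svd = unit_norm(u), v_svd = unit_norm(v))
}

#' Initial canonical vectors from the means of K
#'
#' The iteration is started from the standardized row and column means of
#' `K`: `u0` is the unit-normalized vector of row means (length p, one
#' entry per TF) and `v0` the unit-normalized vector of column means
#' (length q, one per target).  If either mean vector is identically zero
#' the corresponding SVD reference vector is used instead, with a warning.
#'
#' @inheritParams svd_reference_vectors
#' @return A list with unit-norm vectors `u0` (length p) and `v0`
#'   (length q).
#' @export
initial_vectors <- function(K) {
  K <- as.matrix(K)
  if (anyNA(K)) stop("K contains NA entries")
  if (all(K == 0)) stop("K is identically zero; no singular structure")
  u0 <- rowMeans(K)
  v0 <- colMeans(K)
  if (all(u0 == 0) || all(v0 == 0)) {
    ref <- svd_reference_vectors(K)
    if (all(u0 == 0)) {
      warning("row means of K are all zero; falling back to SVD vector for u0")
      u0 <- ref$u_svd
    }
    if (all(v0 == 0)) {
      warning("column means of K are all zero; falling back to SVD vector for v0")
      v0 <- ref$v_svd
    }
  }
  list(u0 = unit_norm(u0), v0 = unit_norm(v0))
}

#' Adaptive soft-thresholding operator
#'
#' Element-wise shrinkage `sign(w_j) * max(|w_j| - lam / (2 |ref_j|^gamma), 0)`.
#' With `gamma = 0` this is uniform soft-thresholding at `lam / 2`
#' regardless of `ref`; with `gamma > 0`, components whose reference
#' weight is exactly zero face an infinite threshold and are forced to
#' zero whenever `lam > 0`.
#'
#' @param w numeric vector to shrink.
#' @param ref reference weight vector of the same length (typically a
#'   first singular vector).
#' @param lam nonnegative penalty.
#' @param gamma nonnegative adaptivity exponent.
#' @return Numeric vector of the same length as `w`.
#' @export
adaptive_soft_threshold <- function(w, ref, lam, gamma) {
  stopifnot(length(w) == length(ref), lam >= 0, gamma >= 0)
  if (lam == 0) return(w)
  if (gamma == 0) {
    thr <- rep(lam / 2, length(w))
  } else {
    thr <- ifelse(ref == 0, Inf, lam / (2 * abs(ref)^gamma))
  }
  out <- pmax(abs(w) - thr, 0) * sign(w)
  out[!is.finite(thr) & lam > 0] <- 0
  out
}

#' Penalty parameter triple
#'
#' @param lambda_u,lambda_v nonnegative L1 penalties on the TF and target
#'   canonical vectors.
#' @param gamma nonnegative adaptivity exponent.
#' @return A list of class `penalty_params`.
#' @export
penalty_params <- function(lambda_u, lambda_v, gamma) {
  stopifnot(lambda_u >= 0, lambda_v >= 0, gamma >= 0)
  structure(list(lambda_u = lambda_u, lambda_v = lambda_v, gamma = gamma),
            class = "penalty_params")
}

#' @export
print.penalty_params <- function(x, ...) {
  cat(sprintf("<penalty_params> lambda_u=%g lambda_v=%g gamma=%g\n",
              x$lambda_u, x$lambda_v, x$gamma))
  invisible(x)
}

#' Enumerate the penalty search grid
#'
#' Cartesian product of `lambda_u`, `lambda_v` and `gamma` values from 0
#' to the given maxima, endpoints included.  Values are generated by
#' index arithmetic (`i * step`) so the grid size is exact and free of
#' floating-point accumulation drift.  The defaults enumerate the full
#' 41 x 41 x 21 = 35301 search space.
#'
#' @param lu_max,lu_step,lv_max,lv_step grid maxima and steps for the two
#'   L1 penalties (defaults 0.4 by 0.01).
#' @param g_max,g_step grid maximum and step for the adaptivity exponent
#'   (defaults 2.0 by 0.1).
#' @return A data.frame of class `penalty_grid` with columns `lambda_u`,
#'   `lambda_v`, `gamma`, one row per triple.
#' @export
penalty_grid <- function(lu_max = 0.4, lu_step = 0.01,
                         lv_max = 0.4, lv_step = 0.01,
                         g_max = 2.0, g_step = 0.1) {
  stopifnot(lu_step > 0, lv_step > 0, g_step > 0,
            lu_max >= 0, lv_max >= 0, g_max >= 0)
  idx <- function(mx, st) (0:floor(mx / st + 1e-9)) * st
  g <- expand.grid(lambda_u = idx(lu_max, lu_step),
                   lambda_v = idx(lv_max, lv_step),
                   gamma = idx(g_max, g_step),
                   KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("penalty_grid", "data.frame")
  g
}

#' Coarse penalty grid for routine runs
#'
#' A 9 x 9 x 5 subsample of the full grid (lambda in steps of 0.05, gamma
#' in steps of 0.5) used as the default inside the cluster-bait loop,
#' where the full 35301-triple grid is affordable but rarely changes the
#' selected model.
#'
#' @return A `penalty_grid` data.frame with 405 rows.
#' @export
coarse_penalty_grid <- function() {
  penalty_grid(lu_step = 0.05, lv_step = 0.05, g_step = 0.5)
}

#' First sparse canonical pair by adaptive soft-thresholded iteration
#'
#' Alternating iteration for the first sparse canonical vector pair of a
#' cross-correlation matrix `K`.  Each sweep performs, for `u`:
#' `u <- K v`, normalize, adaptively soft-threshold against `u_svd`,
#' normalize; and symmetrically for `v` with `t(K) u` and `v_svd`.  The
#' sweep repeats until the max-norm change of both vectors drops below
#' `tol` or `max_iter` is reached.  At zero penalty this is exactly the
#' power iteration for the first singular pair of `K`.
#'
#' If thresholding annihilates `u` or `v` entirely, the fit is returned
#' with empty support and `converged = FALSE`: heavy penalties
#' legitimately produce empty models during grid search, and callers
#' treat the result as "nothing hooked".
#'
#' @param K numeric p x q cross-correlation matrix.
#' @param params a [penalty_params()] triple.
#' @param weights SVD reference weights, as from [svd_reference_vectors()];
#'   computed from `K` when `NULL`.
#' @param u0,v0 starting vectors; the standardized row/column means of
#'   `K` (see [initial_vectors()]) when `NULL`.
#' @param tol convergence tolerance on the max-norm change (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return A list of class `sparse_canonical_pair`: unit-norm sparse
#'   vectors `u` (length p) and `v` (length q), integer index vectors
#'   `support_u` and `support_v`, `n_iterations`, and `converged`.
#' @export
ascca_iterate <- function(K, params, weights = NULL, u0 = NULL, v0 = NULL,
                          tol = 1e-6, max_iter = 500L) {
  K <- as.matrix(K)
  storage.mode(K) <- "double"
  if (anyNA(K)) stop("K contains NA entries")
  stopifnot(inherits(params, "penalty_params"), tol > 0, max_iter >= 1)
  if (is.null(weights)) weights <- svd_reference_vectors(K)
  if (is.null(u0) || is.null(v0)) {
    init <- initial_vectors(K)
    u0 <- u0 %||% init$u0
    v0 <- v0 %||% init$v0
  }
  stopifnot(length(u0) == nrow(K), length(v0) == ncol(K),
            length(weights$u_svd) == nrow(K), length(weights$v_svd) == ncol(K))
  fit <- ascca_grid_cpp(K, weights$u_svd, weights$v_svd,
                        as.numeric(u0), as.numeric(v0),
                        params$lambda_u, params$lambda_v, params$gamma,
                        tol, as.integer(max_iter))
  u <- drop(fit$U)
  v <- drop(fit$V)
  names(u) <- rownames(K)
  names(v) <- colnames(K)
  structure(
    list(u = u, v = v,
         support_u = which(u != 0), support_v = which(v != 0),
         n_iterations = fit$iterations[1L],
         converged = fit$converged[1L],
         params = params),
    class = "sparse_canonical_pair"
  )
}

#' @export
print.sparse_canonical_pair <- function(x, ...) {
  cat(sprintf(
    "<sparse_canonical_pair> |support_u|=%d/%d |support_v|=%d/%d %s (%d iter)\n",
    length(x$support_u), length(x$u), length(x$support_v), length(x$v),
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

# Fit every triple of a grid on one K; returns matrices of u and v
# (one column per triple) plus convergence bookkeeping.
ascca_fit_grid <- function(K, grid, weights = NULL, u0 = NULL, v0 = NULL,
                           tol = 1e-6, max_iter = 500L) {
  K <- as.matrix(K)
  storage.mode(K) <- "double"
  if (is.null(weights)) weights <- svd_reference_vectors(K)
  if (is.null(u0) || is.null(v0)) {
    init <- initial_vectors(K)
    u0 <- u0 %||% init$u0
    v0 <- v0 %||% init$v0
  }
  ascca_grid_cpp(K, weights$u_svd, weights$v_svd,
                 as.numeric(u0), as.numeric(v0),
                 as.numeric(grid$lambda_u), as.numeric(grid$lambda_v),
                 as.numeric(grid$gamma), tol, as.integer(max_iter))
}

#' Cross-validated penalty selection
#'
#' Selects the penalty triple maximizing the held-out canonical
#' correlation.  Samples are partitioned into `k` folds by a seeded
#' shuffle; for each fold the cross-correlation matrix, its SVD reference
#' weights and the initial vectors are recomputed on the training samples
#' only, every triple of the grid is fit there, and the held-out variates
#' `X_test u` and `Y_test v` are correlated.  The criterion is
#' `delta_cor = mean over folds of |cor(X_j u_hat, Y_j v_hat)|`, with
#' folds where either variate is constant (including degenerate all-zero
#' fits) contributing 0.  Because columns are standardized, the diagonal
#' variance of each block is the identity and the canonical vectors equal
#' the singular-basis vectors, so the variates are formed directly from
#' `u` and `v`.
#'
#' Ties are broken deterministically toward the smallest `lambda_u`, then
#' `lambda_v`, then `gamma`.
#'
#' @param X,Y standardized [expression_matrix()] blocks over the same
#'   samples (TFs and one target cluster).
#' @param grid a [penalty_grid()] data.frame.
#' @param k number of folds (default 5); requires `n >= 2k`.
#' @param seed integer seed for the fold shuffle.
#' @param tol,max_iter forwarded to the inner fits.
#' @return A list with `best` (a [penalty_params()]), and `results`, a
#'   data.frame with one row per triple holding `delta_cor` plus the
#'   per-fold signed correlations in a matrix column `fold_correlations`.
#' @export
cv_select <- function(X, Y, grid = coarse_penalty_grid(), k = 5L,
                      seed = 1L, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(X, "expression_matrix"), inherits(Y, "expression_matrix"))
  if (nrow(grid) == 0) stop("penalty grid is empty")
  if (k < 2) stop("k-fold CV requires k >= 2")
  n <- nrow(X$values)
  if (k > n) stop("k exceeds the number of samples")
  if (n < 2 * k)
    stop("need n >= 2k samples for ", k, "-fold CV (have n = ", n, ")")
  if (!identical(X$sample_ids, Y$sample_ids))
    stop("sample_ids of X and Y differ")

  perm <- with_preserved_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(k), n)

  G <- nrow(grid)
  fold_cor <- matrix(0, nrow = G, ncol = k)
  for (j in seq_len(k)) {
    test <- fold_of == j
    Xtr <- X$values[!test, , drop = FALSE]
    Ytr <- Y$values[!test, , drop = FALSE]
    # Pearson cross-correlation recomputed on training rows; columns that
    # happen to be constant within the fold carry no information -> 0.
    Ktr <- suppressWarnings(stats::cor(Xtr, Ytr))
    Ktr[!is.finite(Ktr)] <- 0
    if (all(Ktr == 0)) next
    fit <- ascca_fit_grid(Ktr, grid, tol = tol, max_iter = max_iter)
    Ute <- X$values[test, , drop = FALSE] %*% fit$U
    Vte <- Y$values[test, , drop = FALSE] %*% fit$V
    fold_cor[, j] <- paired_col_cors(Ute, Vte)
  }

  delta <- rowMeans(abs(fold_cor))
  ord <- order(-delta, grid$lambda_u, grid$lambda_v, grid$gamma)
  best_row <- ord[1L]
  results <- data.frame(lambda_u = grid$lambda_u,
                        lambda_v = grid$lambda_v,
                        gamma = grid$gamma,
                        delta_cor = delta)
  results$fold_correlations <- fold_cor
  list(best = penalty_params(grid$lambda_u[best_row],
                             grid$lambda_v[best_row],
                             grid$gamma[best_row]),
       results = results)
}
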