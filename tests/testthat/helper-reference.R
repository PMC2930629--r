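# Independent reference implementations used as oracles.  These are kept
# deliberately naive (plain R, no shared code with the package internals
# beyond the exported API being tested against them).

ref_unit <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}

# First singular pair via eigendecomposition of the Gram matrices.
ref_first_svd_pair <- function(K) {
  eu <- eigen(K %*% t(K), symmetric = TRUE)
  ev <- eigen(t(K) %*% K, symmetric = TRUE)
  u <- eu$vectors[, 1]
  v <- ev$vectors[, 1]
  # align v's sign with u through K
  if (sum((t(K) %*% u) * v) < 0) v <- -v
  if (u[which.max(abs(u))] < 0) {
    u <- -u
    v <- -v
  }
  list(u = u, v = v)
}

# Plain-R transcription of the alternating adaptive soft-thresholding
# iteration, asserting unit norm after every half-step.  Serves as the
# dual route against the compiled implementation.
ref_ascca <- function(K, lambda_u, lambda_v, gamma, tol = 1e-6,
                      max_iter = 500L) {
  sv <- svd(K, nu = 1, nv = 1)
  usvd <- drop(sv$u)
  vsvd <- drop(sv$v)
  if (usvd[which.max(abs(usvd))] < 0) {
    usvd <- -usvd
    vsvd <- -vsvd
  }
  thr <- function(ref, lam) {
    if (lam == 0) return(rep(0, length(ref)))
    if (gamma == 0) return(rep(lam / 2, length(ref)))
    ifelse(ref == 0, Inf, lam / (2 * abs(ref)^gamma))
  }
  tu <- thr(usvd, lambda_u)
  tv <- thr(vsvd, lambda_v)
  soft <- function(x, t) {
    out <- sign(x) * pmax(abs(x) - t, 0)
    out[is.infinite(t)] <- 0
    out
  }
  u <- ref_unit(rowMeans(K))
  v <- ref_unit(colMeans(K))
  for (it in seq_len(max_iter)) {
    un <- drop(K %*% v)
    if (all(un == 0)) return(list(u = u * 0, v = v * 0, converged = FALSE))
    un <- ref_unit(un)
    un <- soft(un, tu)
    if (all(un == 0)) return(list(u = u * 0, v = v * 0, converged = FALSE))
    un <- ref_unit(un)
    stopifnot(abs(sqrt(sum(un^2)) - 1) < 1e-8)
    vn <- drop(t(K) %*% un)
    if (all(vn == 0)) return(list(u = u * 0, v = v * 0, converged = FALSE))
    vn <- ref_unit(vn)
    vn <- soft(vn, tv)
    if (all(vn == 0)) return(list(u = u * 0, v = v * 0, converged = FALSE))
    vn <- ref_unit(vn)
    stopifnot(abs(sqrt(sum(vn^2)) - 1) < 1e-8)
    delta <- max(max(abs(un - u)), max(abs(vn - v)))
    u <- un
    v <- vn
    if (delta < tol) return(list(u = u, v = v, converged = TRUE,
                                 iterations = it))
  }
  list(u = u, v = v, converged = FALSE, iterations = max_iter)
}

# Classical no-ties Spearman formula.
ref_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Agreement up to a global sign flip.
expect_equal_up_to_sign <- function(got, want, tol) {
  d <- min(max(abs(got - want)), max(abs(got + want)))
  expect_lt(d, tol)
}

random_K <- function(p, q) {
  matrix(stats::rnorm(p * q), nrow = p, ncol = q)
}

# Small planted dataset + config for fast pipeline-level tests.
tiny_pipeline_fixture <- function(seed = 1L, noise_sd = 0.05,
                                  mixed_sign = FALSE, n_samples = 40L,
                                  tfs_per_module = 3L, n_decoy_tfs = 30L) {
  ds <- simulate_regulatory_dataset(
    n_samples = n_samples, n_modules = 1L, tfs_per_module = tfs_per_module,
    targets_per_module = 8L, n_decoy_tfs = n_decoy_tfs, noise_sd = noise_sd,
    mixed_sign = mixed_sign, seed = seed)
  cfg <- pipeline_config(
    s_min = 4L, s_max = 8L,
    grid = penalty_grid(0.2, 0.1, 0.2, 0.1, 1, 0.5),
    seed = seed, top_k = 10L, run_ice = FALSE)
  list(ds = ds, cfg = cfg)
}
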