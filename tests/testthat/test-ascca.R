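test_that("svd_reference_vectors matches a Gram-matrix eigendecomposition", {
  # rank-1: K = 2 a b' must return (a, b) under the sign convention
  a <- ref_unit(c(0.8, 0.6, 0))
  b <- ref_unit(c(1, 2) / sqrt(5))
  w <- svd_reference_vectors(2 * outer(a, b))
  expect_equal(w$u_svd, a, tolerance = 1e-10)
  expect_equal(w$v_svd, b, tolerance = 1e-10)

  w <- svd_reference_vectors(rbind(c(1, 0), c(0, 0.5)))
  expect_equal(w$u_svd, c(1, 0), tolerance = 1e-12)
  expect_equal(w$v_svd, c(1, 0), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:5) {
    K <- random_K(5, 4)
    w <- svd_reference_vectors(K)
    o <- ref_first_svd_pair(K)
    expect_equal(w$u_svd, o$u, tolerance = 1e-8)
    expect_equal(w$v_svd, o$v, tolerance = 1e-8)
    expect_equal(sum(w$u_svd^2), 1, tolerance = 1e-10)
    expect_gt(w$u_svd[which.max(abs(w$u_svd))], 0)
  }
  expect_error(svd_reference_vectors(matrix(0, 2, 2)), "zero")
})

test_that("initial_vectors are the normalized row/column means of K", {
  init <- initial_vectors(matrix(0.5, 3, 2))
  expect_equal(init$u0, rep(1, 3) / sqrt(3))
  expect_equal(init$v0, rep(1, 2) / sqrt(2))

  init <- initial_vectors(diag(2))
  expect_equal(init$u0, c(1, 1) / sqrt(2))

  set.seed(7)
  K <- random_K(4, 3)
  init <- initial_vectors(K)
  expect_equal(init$u0, ref_unit(rowMeans(K)), tolerance = 1e-12)
  expect_equal(init$v0, ref_unit(colMeans(K)), tolerance = 1e-12)

  # zero-mean rows fall back to the SVD vector with a warning
  Kz <- rbind(c(1, -1), c(2, -2))
  expect_warning(init <- initial_vectors(Kz), "row means.*falling back")
  expect_equal(abs(init$u0), abs(svd_reference_vectors(Kz)$u_svd),
               tolerance = 1e-10)
  expect_equal(init$v0, ref_unit(colMeans(Kz)), tolerance = 1e-12)
})

test_that("adaptive_soft_threshold implements the penalty formula", {
  # uniform threshold lam/2 at gamma = 0
  expect_equal(adaptive_soft_threshold(0.5, ref = 99, lam = 0.4, gamma = 0),
               0.3)
  # identity at zero penalty
  w <- c(-0.4, 0, 0.9)
  expect_identical(adaptive_soft_threshold(w, w, lam = 0, gamma = 1.3), w)
  # hand arithmetic: thr = 0.1 / 0.5 = 0.2 -> -(0.3 - 0.2)
  expect_equal(adaptive_soft_threshold(-0.3, ref = 0.5, lam = 0.2, gamma = 1),
               -0.1)
  # zero reference weight pins the coefficient at zero when gamma > 0
  expect_equal(adaptive_soft_threshold(c(0.9, 0.9), c(0, 0.5),
                                       lam = 0.1, gamma = 1),
               c(0, 0.8))
  # sign preservation and total shrinkage
  expect_equal(adaptive_soft_threshold(c(-0.05, 0.05), c(1, 1),
                                       lam = 0.2, gamma = 0),
               c(0, 0))
})

test_that("zero-penalty iteration reproduces the first singular pair", {
  set.seed(11)
  for (i in 1:10) {
    K <- random_K(sample(3:12, 1), sample(2:10, 1))
    fit <- ascca_iterate(K, penalty_params(0, 0, 0),
                         tol = 1e-12, max_iter = 20000L)
    o <- ref_first_svd_pair(K)
    expect_true(fit$converged)
    expect_equal_up_to_sign(fit$u, o$u, 1e-6)
    expect_equal_up_to_sign(fit$v, o$v, 1e-6)
  }
})

test_that("rank-1 K with moderate penalties recovers the planted supports", {
  a <- c(0.8, 0.6, 0, 0)        # unit norm, sparse
  b <- c(0.6, 0.8, 0)
  K <- 1.5 * outer(a, b)
  fit <- ascca_iterate(K, penalty_params(0.1, 0.1, 1))
  expect_true(fit$converged)
  expect_equal(unname(fit$support_u), c(1L, 2L))
  expect_equal(unname(fit$support_v), c(1L, 2L))
  expect_equal(sum(fit$u^2), 1, tolerance = 1e-8)
  expect_equal(sum(fit$v^2), 1, tolerance = 1e-8)
})

test_that("total shrinkage yields an empty, non-converged fit", {
  set.seed(3)
  K <- random_K(6, 4)
  fit <- ascca_iterate(K, penalty_params(50, 0, 0))
  expect_false(fit$converged)
  expect_length(fit$support_u, 0)
  expect_length(fit$support_v, 0)
  expect_true(all(fit$u == 0))
})

test_that("compiled fits agree with the plain-R reference across penalties", {
  set.seed(21)
  for (i in 1:8) {
    K <- random_K(sample(4:15, 1), sample(3:8, 1))
    lu <- sample(c(0, 0.05, 0.1, 0.3), 1)
    lv <- sample(c(0, 0.05, 0.1, 0.3), 1)
    g <- sample(c(0, 0.5, 1, 2), 1)
    fit <- ascca_iterate(K, penalty_params(lu, lv, g))
    ref <- ref_ascca(K, lu, lv, g)
    expect_equal(fit$converged, ref$converged)
    expect_equal(unname(fit$u), ref$u, tolerance = 1e-6)
    expect_equal(unname(fit$v), ref$v, tolerance = 1e-6)
  }
})

test_that("transposing K and swapping penalties swaps the solution", {
  set.seed(5)
  K <- random_K(8, 5)
  f1 <- ascca_iterate(K, penalty_params(0.1, 0.05, 1), tol = 1e-10)
  f2 <- ascca_iterate(t(K), penalty_params(0.05, 0.1, 1), tol = 1e-10)
  expect_equal_up_to_sign(unname(f2$u), unname(f1$v), 1e-8)
  expect_equal_up_to_sign(unname(f2$v), unname(f1$u), 1e-8)
})

test_that("penalty_grid enumerates exact Cartesian products", {
  g <- penalty_grid(0.02, 0.01, 0.02, 0.01, 0.1, 0.1)
  expect_equal(nrow(g), 3 * 3 * 2)
  expect_setequal(unique(g$lambda_u), c(0, 0.01, 0.02))
  expect_setequal(unique(g$gamma), c(0, 0.1))
  expect_equal(nrow(penalty_grid(0, 0.01, 0, 0.01, 0, 0.1)), 1L)
  expect_equal(nrow(coarse_penalty_grid()), 9 * 9 * 5)
})

test_that("cv_select maximizes held-out correlation deterministically", {
  set.seed(9)
  n <- 30
  X <- expression_matrix(matrix(rnorm(n * 4), n, 4,
                                dimnames = list(NULL, paste0("tf", 1:4))))
  Xs <- standardize(X)
  Y <- expression_matrix(Xs$values,
                         gene_ids = paste0("tgt", 1:4),
                         standardized = TRUE)

  # single-triple grid is returned unconditionally
  g1 <- penalty_grid(0, 1, 0, 1, 0, 1)
  sel <- cv_select(Xs, Y, grid = g1, k = 5, seed = 1)
  expect_equal(sel$best$lambda_u, 0)
  expect_equal(nrow(sel$results), 1L)

  # Y an exact duplicate of X: perfect canonical correlation at lambda = 0
  expect_equal(sel$results$delta_cor[1], 1, tolerance = 1e-6)

  # determinism: identical calls give identical selections and tables
  g <- penalty_grid(0.2, 0.2, 0.2, 0.2, 1, 1)
  s1 <- cv_select(Xs, Y, grid = g, k = 5, seed = 42)
  s2 <- cv_select(Xs, Y, grid = g, k = 5, seed = 42)
  expect_identical(s1$best, s2$best)
  expect_identical(s1$results$delta_cor, s2$results$delta_cor)

  # delta_cor is the mean of |fold correlations|
  expect_equal(s1$results$delta_cor,
               rowMeans(abs(s1$results$fold_correlations)),
               tolerance = 1e-12)

  expect_error(cv_select(Xs, Y, grid = g[0, ], k = 5), "empty")
  expect_error(cv_select(Xs, Y, grid = g, k = 31), "exceeds")
})
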