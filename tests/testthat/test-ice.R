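test_that("spearman_rho matches rank-based definitions", {
  x <- c(0.5, 1.2, 3.1, 4.0)
  expect_equal(spearman_rho(x, x^2), 1)          # rank-identical
  expect_equal(spearman_rho(x, rev(x)), -1)
  # classical no-ties formula: d = (0, -1, 1, 0) -> 1 - 12/60
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(r, 0)
})

test_that("ice_rank counts strict positive-correlation links", {
  set.seed(12)
  n <- 50
  base <- rnorm(n)
  vals <- cbind(pos1 = base + rnorm(n, sd = 0.1),
                pos2 = base + rnorm(n, sd = 0.1),
                pos3 = rnorm(n),
                dup = base + rnorm(n, sd = 0.1),
                noise = rnorm(n))
  em <- expression_matrix(vals)
  res <- ice_rank(subset_genes(em, c("dup", "noise")),
                  subset_genes(em, c("pos1", "pos2", "pos3")))
  expect_equal(res$tf_id[1], "dup")
  expect_gte(res$link_count[res$tf_id == "dup"], 2L)
  expect_equal(res$link_count[res$tf_id == "noise"], 0L)
  expect_true(all(res$link_count <= 3L))
  expect_equal(res$rank, 1:2)

  # strict inequality: rho0 = 1 links nothing, even identical profiles
  em2 <- expression_matrix(cbind(a = base, b = base))
  res2 <- ice_rank(subset_genes(em2, "a"), subset_genes(em2, "b"), rho0 = 1)
  expect_equal(res2$link_count, 0L)

  expect_error(ice_rank(subset_genes(em, c("pos1", "noise")),
                        subset_genes(em, c("pos1", "pos2"))), "disjoint")
})

test_that("independent noise candidates average under 0.2 links", {
  set.seed(77)
  links <- replicate(20, {
    vals <- matrix(rnorm(50 * 4), 50, 4,
                   dimnames = list(NULL, c("cand", "p1", "p2", "p3")))
    em <- expression_matrix(vals)
    ice_rank(subset_genes(em, "cand"),
             subset_genes(em, c("p1", "p2", "p3")))$link_count
  })
  expect_lt(mean(links), 0.2)
})

test_that("link counts are invariant to strictly increasing transforms", {
  set.seed(13)
  n <- 40
  base <- rnorm(n)
  vals <- cbind(c1 = base + rnorm(n, 0.2), c2 = rnorm(n),
                p1 = base + rnorm(n, 0.2), p2 = base + rnorm(n, 0.2))
  em1 <- expression_matrix(vals)
  vals2 <- vals
  vals2[, "c1"] <- exp(vals2[, "c1"])          # strictly increasing
  vals2[, "p2"] <- vals2[, "p2"]^3 + 5 * vals2[, "p2"]
  em2 <- expression_matrix(vals2)
  r1 <- ice_rank(subset_genes(em1, c("c1", "c2")),
                 subset_genes(em1, c("p1", "p2")))
  r2 <- ice_rank(subset_genes(em2, c("c1", "c2")),
                 subset_genes(em2, c("p1", "p2")))
  expect_identical(r1[c("tf_id", "link_count")], r2[c("tf_id", "link_count")])
})

test_that("a noisy monotone copy of every positive attains rank 1", {
  set.seed(14)
  n <- 60
  pos <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("p", 1:3)))
  shared <- rowMeans(pos)
  vals <- cbind(pos,
                star = shared,
                matrix(rnorm(n * 10), n, 10,
                       dimnames = list(NULL, paste0("d", 1:10))))
  em <- expression_matrix(vals)
  res <- ice_rank(subset_genes(em, c("star", paste0("d", 1:10))),
                  subset_genes(em, paste0("p", 1:3)), rho0 = 0.3)
  expect_equal(res$tf_id[1], "star")
})
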