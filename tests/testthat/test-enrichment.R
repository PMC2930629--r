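test_that("enrichment_filter applies the strict EF threshold", {
  pos <- sprintf("P%02d", 1:13)
  universe_n <- 1638
  hooked <- c(pos[1:2], sprintf("X%02d", 1:48))   # 50 TFs, 2 positives
  hs <- enrichment_filter(hooked, pos, N = universe_n, EF = 3)
  expect_equal(hs$n_ascca, 50L)
  expect_equal(hs$n_pos_overlap, 2L)
  expect_equal(hs$threshold, 3 * (13 / 1638) * 50, tolerance = 1e-12)
  expect_true(hs$retained)                         # 2 > 1.1905

  # one positive is below the same threshold
  hs1 <- enrichment_filter(c(pos[1], sprintf("X%02d", 1:49)), pos,
                           N = universe_n, EF = 3)
  expect_false(hs1$retained)

  # empty set: 0 > 0 is false
  hs0 <- enrichment_filter(character(0), pos, N = universe_n)
  expect_false(hs0$retained)

  # boundary: overlap exactly equal to the threshold is discarded
  hsb <- enrichment_filter(c("P1", "X1"), c("P1", "P2"), N = 4, EF = 1)
  expect_equal(hsb$threshold, 1)
  expect_false(hsb$retained)

  expect_error(enrichment_filter("A", "P1", N = 0), "positive")
  expect_warning(enrichment_filter("A", character(0), N = 10), "discarded")
})

test_that("retention is monotone non-increasing in EF", {
  set.seed(8)
  pos <- sprintf("P%d", 1:5)
  for (i in 1:20) {
    hooked <- sample(c(pos, sprintf("X%d", 1:45)), sample(1:30, 1))
    kept <- sapply(seq(1, 5, by = 0.5), function(ef) {
      enrichment_filter(hooked, pos, N = 50, EF = ef)$retained
    })
    expect_true(all(diff(as.integer(kept)) <= 0))
  }
})

hs_of <- function(ids, retained) {
  hs <- enrichment_filter(ids, character(0) , N = 10) |> suppressWarnings()
  hs$retained <- retained
  hs
}

test_that("frequency_rank pools retained sets only, with stable ties", {
  r <- frequency_rank(list(hs_of(c("A", "B"), TRUE)))
  expect_equal(r$tf_id, c("A", "B"))
  expect_equal(r$frequency, c(1L, 1L))
  expect_equal(r$rank, 1:2)

  r <- frequency_rank(list(hs_of(c("A", "B"), TRUE),
                           hs_of(c("A", "C"), TRUE),
                           hs_of("A", TRUE)))
  expect_equal(r$tf_id[1], "A")
  expect_equal(r$frequency, c(3L, 1L, 1L))

  # discarded sets contribute nothing
  r <- frequency_rank(list(hs_of(c("A", "B"), TRUE),
                           hs_of(c("B", "C"), FALSE)))
  expect_equal(r$tf_id, c("A", "B"))
  expect_equal(r$frequency[r$tf_id == "B"], 1L)
  expect_false("C" %in% r$tf_id)

  # known positives are flagged
  r <- frequency_rank(list(hs_of(c("A", "B"), TRUE)), positive_tf_ids = "B")
  expect_equal(r$is_known_positive, c(FALSE, TRUE))

  expect_equal(nrow(frequency_rank(list())), 0L)
})

test_that("frequency_rank is permutation-stable and conserves counts", {
  set.seed(31)
  sets <- lapply(1:12, function(i) {
    hs_of(sample(LETTERS[1:10], sample(1:6, 1)), retained = i %% 3 != 0)
  })
  r1 <- frequency_rank(sets)
  r2 <- frequency_rank(rev(sets))
  expect_identical(r1, r2)
  kept <- Filter(function(s) s$retained, sets)
  expect_equal(sum(r1$frequency), sum(sapply(kept, `[[`, "n_ascca")))
})

test_that("top_k preserves order and truncates", {
  r <- frequency_rank(list(hs_of(LETTERS[1:5], TRUE)))
  expect_equal(nrow(top_k(r, 70)), 5L)
  expect_equal(top_k(r, 2)$tf_id, c("A", "B"))
  expect_equal(top_k(r, 1)$tf_id, "A")
})
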