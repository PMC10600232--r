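make_acrs <- function(chrom, start, end, score) {
  data.frame(acr_id = paste0("a", seq_along(start)), chrom = chrom,
             start = start, end = end, score = score,
             level = "sample", stringsAsFactors = FALSE)
}

test_that("summit extension produces 501-bp windows and clamps at zero", {
  p <- data.frame(chrom = "chr1", summit = c(1000L, 100L, 5000L),
                  score = c(10, 5, 2), sample_id = "s1")
  a <- summit_to_acr(p, halfwidth = 250)
  expect_equal(a$start, c(750L, 0L, 4750L))
  expect_equal(a$end, c(1251L, 351L, 5251L))
  expect_equal(a$end - a$start, c(501L, 351L, 501L))
  expect_equal(a$truncated, c(FALSE, TRUE, FALSE))
  expect_equal(a$score, p$score)

  a0 <- summit_to_acr(p[1, ], halfwidth = 0)
  expect_equal(c(a0$start, a0$end), c(1000L, 1001L))
})

test_that("greedy selection keeps the most significant of overlapping ACRs", {
  acrs <- make_acrs("chr1", c(0, 400, 2000), c(500, 900, 2500), c(10, 5, 1))
  kept <- select_nonoverlapping(acrs, "score")
  expect_equal(kept$acr_id, c("a1", "a3"))

  disjoint <- make_acrs("chr1", c(0, 1000, 2000), c(500, 1500, 2500), 1:3)
  expect_equal(nrow(select_nonoverlapping(disjoint, "score")), 3L)

  # equal scores: leftmost (chrom, start) wins
  tie <- make_acrs("chr1", c(100, 0), c(600, 500), c(7, 7))
  expect_equal(select_nonoverlapping(tie, "score")$acr_id, "a2")
})

test_that("greedy selection matches the brute-force oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:50) {
    acrs <- random_acr_set(sample(2:20, 1))
    got <- select_nonoverlapping(acrs, "score")
    want <- acrs[oracle_greedy_select(acrs, "score"), ]
    expect_setequal(got$acr_id, want$acr_id)
    expect_identical(select_nonoverlapping(got, "score")$acr_id,
                     got$acr_id)
    # output pairwise non-overlapping
    self <- intervals_overlap(got, got)
    expect_true(all(self$query == self$subject))
  }
})

test_that("score-per-million normalization is proportional and conserved", {
  acrs <- make_acrs("chr1", c(0, 1000, 2000), c(500, 1500, 2500), c(2, 3, 5))
  n <- normalize_score_per_million(acrs)
  expect_equal(n$norm_score, c(2e5, 3e5, 5e5))
  expect_equal(sum(n$norm_score), 1e6)

  one <- normalize_score_per_million(acrs[1, ])
  expect_equal(one$norm_score, 1e6)

  equal4 <- make_acrs("chr1", c(0, 1, 2, 3) * 1000,
                      c(0, 1, 2, 3) * 1000 + 500, rep(1, 4))
  expect_equal(normalize_score_per_million(equal4)$norm_score, rep(2.5e5, 4))

  expect_error(normalize_score_per_million(acrs[0, ]), "empty")
  zero <- transform(acrs, score = 0)
  expect_error(normalize_score_per_million(zero), "positive")
})

test_that("merging pools normalized sets and resolves by normalized score", {
  set1 <- normalize_score_per_million(
    make_acrs("chr1", c(0, 1000), c(501, 1501), c(6, 4)))
  set2 <- normalize_score_per_million(
    make_acrs("chr1", 400, 901, 5))
  merged <- merge_acr_sets(list(set1, set2))
  expect_equal(sort(merged$start), c(400, 1000))  # 1e6 beats 6e5
  expect_true(all(merged$level == "patient"))

  # disjoint sets union
  s1 <- normalize_score_per_million(make_acrs("chr1", 0, 501, 3))
  s2 <- normalize_score_per_million(make_acrs("chr2", 0, 501, 9))
  expect_equal(nrow(merge_acr_sets(list(s1, s2))), 2L)

  # single set passes through with promoted level
  solo <- merge_acr_sets(list(set1))
  expect_equal(solo$start, set1$start)
  expect_true(all(solo$level == "patient"))

  expect_error(merge_acr_sets(list(make_acrs("chr1", 0, 501, 3))),
               "not score-per-million normalized")
})

test_that("merging is order-insensitive for disjoint sets and agrees with the oracle", {
  set.seed(9)
  for (rep in 1:20) {
    s1 <- normalize_score_per_million(random_acr_set(8, chroms = "c1"))
    s2 <- normalize_score_per_million(random_acr_set(8, chroms = "c2"))
    s1 <- normalize_score_per_million(select_nonoverlapping(s1, "score"))
    s2 <- normalize_score_per_million(select_nonoverlapping(s2, "score"))
    ab <- merge_acr_sets(list(s1, s2))
    ba <- merge_acr_sets(list(s2, s1))
    expect_setequal(paste(ab$chrom, ab$start), paste(ba$chrom, ba$start))

    pooled <- rbind(s1, s2)
    want <- pooled[oracle_greedy_select(pooled, "norm_score"), ]
    expect_setequal(paste(ab$chrom, ab$start),
                    paste(want$chrom, want$start))
  }
})

test_that("CPM columns are scaled per million and zero columns rejected", {
  m <- matrix(c(1, 1, 2, 0, 0, 4), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cpm <- compute_cpm(m)
  expect_equal(cpm[, "s1"], c(a = 250000, b = 250000, c = 500000))
  expect_equal(cpm[, "s2"], c(a = 0, b = 0, c = 1e6))

  set.seed(5)
  big <- matrix(rpois(250, 20), nrow = 50,
                dimnames = list(paste0("a", 1:50), paste0("s", 1:5)))
  expect_equal(unname(colSums(compute_cpm(big))), rep(1e6, 5))

  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "sick"))
  expect_error(compute_cpm(zero), "sick")
})

test_that("recurrence filter applies strict log2 CPM threshold per sample", {
  cpm <- matrix(c(2.0, 0.5, 3.0,
                  2.0, 0.5, 0.5,
                  0.0, 0.0, 0.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("keep", "drop", "zero"), paste0("s", 1:3)))
  expect_equal(filter_recurrent(cpm), "keep")
  expect_equal(filter_recurrent(cpm, min_samples = 0),
               c("keep", "drop", "zero"))
  # boundary: log2(cpm) must strictly exceed the threshold
  b <- matrix(c(1, 1, 1), nrow = 1, dimnames = list("b", paste0("s", 1:3)))
  expect_equal(length(filter_recurrent(b)), 0L)
})

test_that("cohort construction yields a non-overlapping landscape", {
  sim <- simulate_cohort(sim_config(seed = 3, n_samples = 6, n_acrs = 150,
                                    n_highsignal = 5))
  pts <- setNames(sim$labels$patient_id, sim$labels$sample_id)
  cohort <- build_cohort_acrs(sim$peaks, pts)
  expect_true(all(cohort$level == "cohort"))
  self <- intervals_overlap(cohort, cohort)
  expect_true(all(self$query == self$subject))
  # every simulated locus is represented by one cohort ACR
  expect_equal(nrow(cohort), nrow(sim$acrs))
})
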