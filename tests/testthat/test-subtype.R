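# CPM value above the log2(CPM) > 1 threshold is anything > 2
HI <- 8
LO <- 0.5

subtype_matrix <- function(n_acr, labels, hi_cells) {
  m <- matrix(LO, nrow = n_acr, ncol = length(labels),
              dimnames = list(paste0("a", seq_len(n_acr)), names(labels)))
  m[hi_cells] <- HI
  m
}

test_that("subtype specificity applies strict in/out fractions", {
  labels <- setNames(rep(c("A", "B"), c(4, 10)), paste0("s", 1:14))
  # 3/4 = 75% of A above, 0/10 of B -> specific
  m <- subtype_matrix(1, labels, cbind(1, 1:3))
  expect_equal(call_subtype_specific(m, labels)$A, "a1")
  # exactly 50% of A -> not specific (strict >)
  m2 <- subtype_matrix(1, labels, cbind(1, 1:2))
  expect_equal(length(call_subtype_specific(m2, labels)$A), 0L)
  # 3/4 in A but exactly 10% of others -> not specific (strict <)
  m3 <- subtype_matrix(1, labels, cbind(1, c(1:3, 5)))
  expect_equal(length(call_subtype_specific(m3, labels)$A), 0L)
  # sample without a label errors
  expect_error(call_subtype_specific(m, labels[-1]), "no subtype label")
})

test_that("subtype calls agree with exhaustive per-ACR fraction oracle", {
  set.seed(14)
  labels <- setNames(sample(c("A", "B", "C"), 12, replace = TRUE),
                     paste0("s", 1:12))
  while (length(unique(labels)) < 3) {
    labels[] <- sample(c("A", "B", "C"), 12, replace = TRUE)
  }
  cpm <- matrix(2^runif(20 * 12, -2, 4), nrow = 20,
                dimnames = list(paste0("a", 1:20), names(labels)))
  got <- call_subtype_specific(cpm, labels)
  for (s in unique(labels)) {
    want <- character()
    for (i in 1:20) {
      fin <- mean(log2(cpm[i, labels == s]) > 1)
      fout <- mean(log2(cpm[i, labels != s]) > 1)
      if (fin > 0.5 && fout < 0.1) want <- c(want, rownames(cpm)[i])
    }
    expect_setequal(got[[s]], want)
  }
})

test_that("motif fractions count specific ACRs carrying each TF hit", {
  specific <- list(A = paste0("a", 1:10), B = character())
  hits <- data.frame(
    acr_id = c(paste0("a", 1:4), paste0("a", 1:10)),
    tf_name = rep(c("TF1", "TF2"), c(4, 10))
  )
  frac <- motif_enrichment_fraction(specific, hits)
  expect_equal(frac["TF1", "A"], 0.4)
  expect_equal(frac["TF2", "A"], 1)
  expect_true(is.na(frac["TF1", "B"]))
  no_hit <- motif_enrichment_fraction(specific,
                                      data.frame(acr_id = "zzz",
                                                 tf_name = "TF9"))
  expect_equal(no_hit["TF9", "A"], 0)
})

test_that("one-sided TF expression test matches the exact rank-sum null", {
  labels <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  fpkm <- matrix(c(8, 9, 10, 1, 2, 3), nrow = 1,
                 dimnames = list("TF1", names(labels)))
  res <- tf_expression_test(fpkm, labels, "TF1", "A", pseudocount = 0)
  expect_equal(res$p, 1 / 20)  # fully separated 3 vs 3
  expect_equal(res$p, oracle_ranksum_greater(c(8, 9, 10), c(1, 2, 3)))
  expect_false(res$passes)  # p = 0.05 sits on the strict boundary

  # identical groups: p >= 0.5, fails
  same <- matrix(rep(c(4, 5, 6), 2), nrow = 1,
                 dimnames = list("TF1", names(labels)))
  res2 <- tf_expression_test(same, labels, "TF1", "A")
  expect_gte(res2$p, 0.5)
  expect_false(res2$passes)

  # fold change of exactly 1.2 fails the strict threshold
  fc12 <- matrix(c(2.4, 2.4, 2.4, 2.0, 2.0, 2.0), nrow = 1,
                 dimnames = list("TF1", names(labels)))
  res3 <- tf_expression_test(fc12, labels, "TF1", "A", pseudocount = 0)
  expect_equal(res3$fc, 1.2)
  expect_false(res3$passes)
})

test_that("TSS-window target assignment is symmetric around the TSS", {
  genes <- gene_models(data.frame(
    chrom = "c1", start = c(5000L, 50000L), end = c(10000L, 55000L),
    strand = c("+", "-"), gene_id = c("gp", "gm"),
    stringsAsFactors = FALSE
  ))
  # gp TSS 5000; gm TSS 54999
  a <- data.frame(acr_id = c("x", "y", "z"), chrom = "c1",
                  start = c(5500, 56200, 30000),
                  end = c(6001, 56701, 30501))
  expect_setequal(tss_window_targets(a[1, ], genes), "gp")   # within 1 kb
  expect_setequal(tss_window_targets(a[2, ], genes), character())  # 1201 bp
  expect_setequal(tss_window_targets(a, genes), "gp")
})

test_that("target aggregation uses geometric-mean p and median log2 FC", {
  labels <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  # two fully separated targets: each exact p = 1/choose(8,4) = 1/70
  fpkm <- rbind(g1 = c(8, 9, 10, 11, 1, 2, 3, 4),
                g2 = c(40, 44, 48, 52, 4, 5, 6, 7))
  colnames(fpkm) <- names(labels)
  agg <- aggregate_target_genes(fpkm, labels, c("g1", "g2"), "A",
                                pseudocount = 0)
  expect_equal(agg$target_p, sqrt((1 / 70) * (1 / 70)))
  expect_equal(agg$target_fc,
               median(c(log2(9.5 / 2.5), log2(46 / 5.5))))
  expect_true(agg$significant)

  # single target: aggregate equals that target's values
  one <- aggregate_target_genes(fpkm, labels, "g1", "A", pseudocount = 0)
  expect_equal(one$target_p, 1 / 70)
  expect_equal(one$target_fc, log2(9.5 / 2.5))

  # permutation invariance and min/max bounds of the geometric mean
  rev2 <- aggregate_target_genes(fpkm, labels, c("g2", "g1"), "A",
                                 pseudocount = 0)
  expect_equal(rev2$target_p, agg$target_p)
  expect_error(aggregate_target_genes(fpkm, labels, character(), "A"),
               "empty")
})

test_that("geometric-mean p is bounded by the per-target extremes", {
  labels <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  set.seed(8)
  for (rep in 1:10) {
    fpkm <- matrix(rlnorm(5 * 8, log(5), 1), nrow = 5,
                   dimnames = list(paste0("g", 1:5), names(labels)))
    p_each <- vapply(rownames(fpkm), function(g) {
      aggregate_target_genes(fpkm, labels, g, "A")$target_p
    }, numeric(1))
    agg <- aggregate_target_genes(fpkm, labels, rownames(fpkm), "A")
    expect_lte(agg$target_p, max(p_each))
    expect_gte(agg$target_p, min(p_each))
  }
})

test_that("planted subtype effects are recovered without cross-calls", {
  sim <- simulate_cohort(sim_config(seed = 1))
  cpm <- compute_cpm(sim$counts)
  rec <- filter_recurrent(cpm)
  spec <- call_subtype_specific(cpm[rec, , drop = FALSE], sim$subtypes)
  truth <- sim$truth$subtype_specific
  hits <- unlist(lapply(names(truth),
                        function(s) truth[[s]] %in% spec[[s]]))
  expect_gte(mean(hits), 0.9)
  planted_all <- unlist(truth)
  cross <- vapply(names(spec), function(s) {
    sum(spec[[s]] %in% setdiff(planted_all, truth[[s]]))
  }, numeric(1))
  expect_equal(sum(cross), 0)
})
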