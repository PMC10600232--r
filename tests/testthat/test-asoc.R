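snp_row <- function(atac_ref, atac_alt, wgs_ref = 15, wgs_alt = 15,
                    chrom = "c1", pos = 1000L, sample_id = "s1") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             wgs_ref = wgs_ref, wgs_alt = wgs_alt,
             atac_ref = atac_ref, atac_alt = atac_alt,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

one_acr <- data.frame(acr_id = "acr1", chrom = "c1",
                      start = 750L, end = 1251L)

test_that("sigma(N) saturates from zero toward its scale", {
  m <- sigma_model()
  expect_equal(sigma_of_coverage(0, m), 0)
  expect_equal(sigma_of_coverage(83, m), 10.8 * (1 - exp(-1)))
  N <- seq(0, 2000, by = 10)
  s <- sigma_of_coverage(N, m)
  expect_true(all(diff(s) > 0))
  expect_true(all(s < 10.8))
  expect_lt(10.8 - sigma_of_coverage(5000, m), 1e-10)
  expect_error(sigma_of_coverage(-1, m), "non-negative")
})

test_that("heterozygous SNP filter applies all four eligibility rules", {
  keep <- snp_row(30, 28, wgs_ref = 12, wgs_alt = 10)  # MAF 0.455
  bad_maf <- snp_row(30, 28, wgs_ref = 20, wgs_alt = 2)  # MAF 0.09
  low_cov <- snp_row(5, 2)                               # coverage 7
  low_alt <- snp_row(28, 2)                              # alt reads 2
  outside <- snp_row(30, 28, pos = 5000L)
  got <- filter_het_snps(rbind(keep, bad_maf, low_cov, low_alt, outside),
                         one_acr)
  expect_equal(nrow(got), 1L)
  expect_equal(got$atac_ref, 30L)
  expect_equal(got$acr_id, "acr1")
  expect_warning(filter_het_snps(snp_row(30, 28, wgs_ref = 0, wgs_alt = 0),
                                 one_acr), "zero WGS depth")
})

test_that("MAF band boundaries are inclusive", {
  lo <- snp_row(30, 28, wgs_ref = 7, wgs_alt = 3)    # MAF 0.30
  hi <- snp_row(30, 28, wgs_ref = 3, wgs_alt = 7)    # MAF 0.70
  out <- snp_row(30, 28, wgs_ref = 29, wgs_alt = 10) # MAF 0.256
  expect_equal(nrow(filter_het_snps(rbind(lo, hi, out), one_acr)), 2L)
})

test_that("imbalance test matches an independent Gaussian evaluation", {
  bal <- test_snp_imbalance(transform(snp_row(50, 50), acr_id = "acr1"))
  expect_equal(bal$af, 0.5)
  expect_equal(bal$delta, 0)
  expect_equal(bal$p, 1)

  skew <- test_snp_imbalance(transform(snp_row(80, 20), acr_id = "acr1"))
  expect_equal(skew$delta, 0.3)
  sigma100 <- 10.8 * (1 - exp(-100 / 83))
  z <- 30 / sigma100
  # independent tail evaluation by numeric integration of the normal density
  tail <- stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-13)$value
  expect_equal(skew$p, 2 * tail, tolerance = 1e-12)

  extreme <- test_snp_imbalance(transform(snp_row(0, 8), acr_id = "acr1"))
  expect_equal(extreme$af, 1)
  expect_equal(extreme$delta, 0.5)
})

test_that("p is monotone in imbalance and in coverage", {
  for (N in c(10, 50, 100, 500)) {
    alt <- seq(ceiling(N / 2), N)
    res <- test_snp_imbalance(
      transform(snp_row(N - alt, alt), acr_id = "acr1"))
    expect_true(all(diff(res$p) <= 1e-15))
  }
  # sigma(N) grows with coverage, so at fixed af the same percentage
  # deviation becomes less surprising as N rises: p is non-decreasing in N
  for (af in c(0.6, 0.8)) {
    Ns <- c(10, 20, 50, 100, 200, 500)
    alt <- round(Ns * af)
    res <- test_snp_imbalance(
      transform(snp_row(Ns - alt, alt), acr_id = "acr1"))
    exact <- res$af == af
    expect_true(all(diff(res$p[exact]) >= -1e-15))
  }
})

test_that("ACR-level combination uses Fisher's method and mean delta", {
  r1 <- transform(snp_row(80, 20), acr_id = "acr1", sample_id = "s1")
  one <- call_acr_asoc(test_snp_imbalance(r1))
  expect_equal(one$combined_p, test_snp_imbalance(r1)$p)  # k = 1 identity
  expect_equal(one$label, "ASOC")

  # two SNPs: chi-square survival oracle on -2 sum(log p)
  two <- rbind(transform(snp_row(80, 20, pos = 900L), acr_id = "acr1"),
               transform(snp_row(30, 60, pos = 1100L), acr_id = "acr1"))
  res <- test_snp_imbalance(two)
  call <- call_acr_asoc(res)
  stat <- -2 * sum(log(res$p))
  expect_equal(call$combined_p,
               stats::pchisq(stat, df = 4, lower.tail = FALSE))
  expect_equal(call$combined_delta, mean(res$delta))
  expect_equal(call$n_snps, 2L)

  # boundary: mean delta exactly 0.2 passes (inclusive >=)
  fake <- data.frame(sample_id = "s1", acr_id = "a", delta = c(0.25, 0.15),
                     p = c(1e-6, 1e-6))
  expect_equal(call_acr_asoc(fake)$label, "ASOC")
  fake$delta <- c(0.25, 0.10)
  expect_equal(call_acr_asoc(fake)$label, "BiOC")
})

test_that("Fisher combination example: p = {0.01, 0.04} on 4 df", {
  fake <- data.frame(sample_id = "s1", acr_id = "a",
                     delta = c(0.3, 0.3), p = c(0.01, 0.04))
  stat <- -2 * (log(0.01) + log(0.04))
  expect_equal(stat, 15.65, tolerance = 1e-3)
  expect_equal(call_acr_asoc(fake)$combined_p,
               stats::pchisq(stat, 4, lower.tail = FALSE))
})

test_that("candidate genes respect distance, flag and expression floor", {
  acrs <- data.frame(acr_id = "acr1", chrom = "c1",
                     start = 499750L, end = 500251L)  # center 500000
  genes <- gene_models(data.frame(
    chrom = "c1",
    start = c(650000L, 750000L, 655000L, 652000L),
    end = c(655000L, 755000L, 660000L, 657000L),
    strand = "+",
    gene_id = c("near", "far", "low", "unflagged"),
    cosmic = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
  fpkm <- matrix(c(2, 2, 0.5, 9), ncol = 1,
                 dimnames = list(genes$gene_id, "s1"))
  calls <- data.frame(sample_id = "s1", acr_id = "acr1", label = "ASOC")
  got <- nearby_expressed_genes(calls, acrs, genes, fpkm)
  expect_equal(got$gene_id, "near")   # 150 kb, FPKM 2, flagged
  none <- nearby_expressed_genes(transform(calls, label = "BiOC"),
                                 acrs, genes, fpkm)
  expect_equal(nrow(none), 0L)
})

test_that("ASOC and BiOC fractions partition the called ACRs", {
  ar <- simulate_allelic_reads(sim_config(seed = 5, n_acrs = 300,
                                          n_planted_asoc = 30))
  calls <- call_acr_asoc(test_snp_imbalance(filter_het_snps(ar$snps,
                                                            ar$acrs)))
  expect_true(all(calls$label %in% c("ASOC", "BiOC")))
  expect_equal(mean(calls$label == "ASOC") + mean(calls$label == "BiOC"), 1)
})
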