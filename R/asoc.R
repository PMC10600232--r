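# Allele-specific open chromatin (ASOC): heterozygous-SNP filtering, the
# coverage-dependent Gaussian imbalance test, SNP -> ACR combination, and
# candidate-gene assignment.

#' Coverage-dependent sigma model for the allelic-imbalance test
#'
#' The standard deviation of the ATAC allele fraction (in percentage points)
#' under the balanced null, as a saturating function of read coverage:
#' `sigma(N) = scale * (1 - exp(-N / rate_coverage))`. The defaults
#' (scale 10.8, rate 83 reads) are the trained constants of the model and
#' are taken as given.
#'
#' @param scale asymptotic standard deviation, percentage points.
#' @param rate_coverage coverage scale of the exponential saturation, reads.
#' @return object of class `sigma_model`.
#' @export
sigma_model <- function(scale = 10.8, rate_coverage = 83) {
  stopifnot(scale > 0, rate_coverage > 0)
  structure(list(scale = scale, rate_coverage = rate_coverage),
            class = "sigma_model")
}

#' Evaluate sigma(N)
#'
#' Strictly increasing in coverage `N`, zero at `N = 0`, bounded above by
#' the model's `scale`.
#'
#' @param N read coverage (non-negative; vectorized).
#' @param model a [sigma_model()].
#' @return standard deviation of the allele fraction, in percentage points.
#' @export
sigma_of_coverage <- function(N, model = sigma_model()) {
  if (any(N < 0)) stop("coverage N must be non-negative")
  model$scale * (1 - exp(-N / model$rate_coverage))
}

#' Filter heterozygous SNPs eligible for the imbalance test
#'
#' Keeps SNPs that (1) are balanced heterozygous in WGS
#' (`maf_low <= wgs_alt / (wgs_ref + wgs_alt) <= maf_high`, inclusive),
#' (2) fall inside an ACR, (3) have ATAC coverage
#' `atac_ref + atac_alt >= min_cov`, and (4) have `atac_alt >= min_alt`
#' (the alt allele literally, not the minor allele). Records with zero WGS
#' depth are dropped with a warning. The containing ACR's id is attached.
#'
#' @param snps data.frame of SNP allelic records (0-based `pos`), as from
#'   [read_allelic_counts()].
#' @param acrs data.frame of ACRs with `acr_id`.
#' @param maf_low,maf_high WGS alt-fraction band for heterozygous sites.
#' @param min_cov minimum ATAC coverage (ref + alt reads).
#' @param min_alt minimum ATAC alt reads.
#' @return eligible subset of `snps` with an `acr_id` column.
#' @export
filter_het_snps <- function(snps, acrs, maf_low = 0.3, maf_high = 0.7,
                            min_cov = 8L, min_alt = 3L) {
  stopifnot(maf_low >= 0, maf_high <= 1, maf_low <= maf_high,
            min_cov >= 0, min_alt >= 0)
  if (nrow(snps) == 0L) {
    snps$acr_id <- character()
    return(snps)
  }
  wgs_total <- snps$wgs_ref + snps$wgs_alt
  if (any(wgs_total == 0L)) {
    warning(sum(wgs_total == 0L), " SNP(s) with zero WGS depth excluded")
  }
  maf <- ifelse(wgs_total > 0L, snps$wgs_alt / wgs_total, NA_real_)
  atac_cov <- snps$atac_ref + snps$atac_alt
  keep <- !is.na(maf) & maf >= maf_low & maf <= maf_high &
    atac_cov >= min_cov & snps$atac_alt >= min_alt
  snps <- snps[keep, , drop = FALSE]
  if (nrow(snps) == 0L) {
    snps$acr_id <- character()
    return(snps)
  }
  pts <- data.frame(chrom = snps$chrom, start = snps$pos,
                    end = snps$pos + 1L)
  ov <- intervals_overlap(pts, acrs)
  ov <- ov[!duplicated(ov$query), , drop = FALSE]  # ACR sets do not overlap
  snps$acr_id <- NA_character_
  snps$acr_id[ov$query] <- acrs$acr_id[ov$subject]
  snps <- snps[!is.na(snps$acr_id), , drop = FALSE]
  rownames(snps) <- NULL
  snps
}

#' Test allelic imbalance at eligible SNPs
#'
#' For each SNP the ATAC alt-allele fraction `af = atac_alt / N`
#' (`N = atac_ref + atac_alt`) is compared to the balanced expectation of
#' 50% under a Gaussian null with coverage-dependent standard deviation
#' [sigma_of_coverage()]: `z = |100 af - 50| / sigma(N)` and
#' `p = 2 (1 - Phi(z))`. `delta = |af - 0.5|`. If `sigma(N) = 0` while
#' `af != 0.5` the p-value is set to the smallest representable positive
#' number and the record flagged.
#'
#' @param snps eligible SNPs from [filter_het_snps()].
#' @param model a [sigma_model()].
#' @return data.frame: the input columns plus `N`, `af`, `delta`, `p`,
#'   `sigma_zero` flag.
#' @export
test_snp_imbalance <- function(snps, model = sigma_model()) {
  N <- snps$atac_ref + snps$atac_alt
  if (any(N <= 0)) stop("eligible SNPs must have positive ATAC coverage")
  af <- snps$atac_alt / N
  sigma <- sigma_of_coverage(N, model)
  z <- abs(100 * af - 50) / sigma
  p <- 2 * stats::pnorm(-z)
  sigma_zero <- sigma == 0 & af != 0.5
  p[sigma_zero] <- .Machine$double.xmin
  p[sigma == 0 & af == 0.5] <- 1
  out <- snps
  out$N <- N
  out$af <- af
  out$delta <- abs(af - 0.5)
  out$p <- p
  out$sigma_zero <- sigma_zero
  out
}

#' Combine SNP-level imbalance into ACR-level ASOC calls
#'
#' Per ACR (within each sample), SNP p-values are combined by Fisher's
#' method (chi-square with `2k` df on `-2 sum(log p)`, p clamped at 1e-300
#' before the log) and deltas by the arithmetic mean. An ACR is labeled
#' `ASOC` when `combined_p < 0.05` and `combined_delta >= 0.2`, otherwise
#' `BiOC`. ACRs without any eligible SNP never appear.
#'
#' @param snp_results data.frame from [test_snp_imbalance()] with `acr_id`
#'   (and `sample_id`).
#' @return data.frame with one row per (sample, ACR): `sample_id`, `acr_id`,
#'   `n_snps`, `combined_p`, `combined_delta`, `label`.
#' @export
call_acr_asoc <- function(snp_results) {
  if (nrow(snp_results) == 0L) {
    return(data.frame(sample_id = character(), acr_id = character(),
                      n_snps = integer(), combined_p = numeric(),
                      combined_delta = numeric(), label = character()))
  }
  key <- paste(snp_results$sample_id, snp_results$acr_id, sep = "\r")
  groups <- split(seq_len(nrow(snp_results)), key)
  rows <- lapply(groups, function(idx) {
    p <- pmax(snp_results$p[idx], 1e-300)
    k <- length(idx)
    combined_p <- if (k == 1L) p else {
      stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
    }
    combined_delta <- mean(snp_results$delta[idx])
    data.frame(
      sample_id = snp_results$sample_id[idx[1L]],
      acr_id = snp_results$acr_id[idx[1L]],
      n_snps = k, combined_p = combined_p,
      combined_delta = combined_delta,
      label = if (combined_p < 0.05 && combined_delta >= 0.2) "ASOC"
              else "BiOC",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate genes near ASOC regions
#'
#' For each ASOC-labeled ACR, reports flagged (e.g. COSMIC) genes whose
#' interval overlaps the window `[center - window, center + window]` around
#' the ACR center and whose expression in the same sample is at least
#' `min_fpkm`.
#'
#' @param asoc_calls data.frame from [call_acr_asoc()] (only rows labeled
#'   `ASOC` are used).
#' @param acrs data.frame of ACRs with `acr_id` coordinates.
#' @param genes gene models with a logical `cosmic` (or other membership)
#'   flag column.
#' @param fpkm expression matrix (genes x samples).
#' @param window distance from ACR center in bp (default 200 kb).
#' @param min_fpkm expression floor in the matched sample.
#' @param flag_col name of the logical membership column in `genes`.
#' @return data.frame with `sample_id`, `acr_id`, `gene_id`.
#' @export
nearby_expressed_genes <- function(asoc_calls, acrs, genes, fpkm,
                                   window = 200000L, min_fpkm = 1,
                                   flag_col = "cosmic") {
  stopifnot(window >= 0, flag_col %in% names(genes))
  calls <- asoc_calls[asoc_calls$label == "ASOC", , drop = FALSE]
  flagged <- genes[isTRUE_vec(genes[[flag_col]]), , drop = FALSE]
  empty <- data.frame(sample_id = character(), acr_id = character(),
                      gene_id = character())
  if (nrow(calls) == 0L || nrow(flagged) == 0L) return(empty)
  i <- match(calls$acr_id, acrs$acr_id)
  if (anyNA(i)) stop("ASOC call references unknown ACR id")
  center <- (acrs$start[i] + acrs$end[i]) %/% 2L
  win <- data.frame(chrom = acrs$chrom[i],
                    start = pmax(0, center - window),
                    end = center + window + 1L)
  ov <- intervals_overlap(win, flagged)
  if (nrow(ov) == 0L) return(empty)
  out <- data.frame(
    sample_id = calls$sample_id[ov$query],
    acr_id = calls$acr_id[ov$query],
    gene_id = flagged$gene_id[ov$subject],
    stringsAsFactors = FALSE
  )
  expr <- fpkm[cbind(match(out$gene_id, rownames(fpkm)),
                     match(out$sample_id, colnames(fpkm)))]
  out <- out[!is.na(expr) & expr >= min_fpkm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
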