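# Subtype-specific ACR calling, TF motif-enrichment fractions, and the
# expression tests for subtype-enriched TFs and their target genes.

check_labels <- function(mat, labels) {
  stopifnot(!is.null(colnames(mat)))
  miss <- setdiff(colnames(mat), names(labels))
  if (length(miss)) {
    stop("no subtype label for sample(s): ", paste(miss, collapse = ", "))
  }
  labels[colnames(mat)]
}

#' Call subtype-specific ACRs
#'
#' An ACR is specific to subtype S when its `log2(CPM)` exceeds
#' `log2cpm_thresh` in strictly more than `in_frac` of the S samples and in
#' strictly less than `out_frac` of all other samples (defaults: > 50% of
#' the subtype, < 10% of the rest, at log2 CPM > 1). Both inequalities are
#' strict, so exact boundary fractions do not qualify.
#'
#' @param cpm CPM matrix (ACRs x samples).
#' @param labels named character vector, sample id -> subtype.
#' @param in_frac minimum (strict) fraction of subtype samples above
#'   threshold.
#' @param out_frac maximum (strict) fraction of other samples above
#'   threshold.
#' @param log2cpm_thresh accessibility threshold on the log2 CPM scale.
#' @return named list, subtype -> character vector of specific ACR ids.
#' @export
call_subtype_specific <- function(cpm, labels, in_frac = 0.50,
                                  out_frac = 0.10, log2cpm_thresh = 1) {
  labels <- check_labels(cpm, labels)
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2L) stop("need at least two subtypes")
  above <- log2(cpm) > log2cpm_thresh
  out <- lapply(subtypes, function(s) {
    inside <- labels == s
    in_share <- rowMeans(above[, inside, drop = FALSE])
    out_share <- rowMeans(above[, !inside, drop = FALSE])
    rownames(cpm)[in_share > in_frac & out_share < out_frac]
  })
  names(out) <- subtypes
  out
}

#' Fraction of subtype-specific ACRs carrying each TF motif
#'
#' For every (TF, subtype) pair: the share of that subtype's specific ACRs
#' that carry at least one motif hit for the TF. Subtypes with no specific
#' ACRs give `NA`.
#'
#' @param specific named list from [call_subtype_specific()].
#' @param hits motif-hit table: data.frame with `acr_id`, `tf_name` (one row
#'   per hit; hits come from external scanning of 101-bp summit-centered
#'   windows).
#' @return numeric matrix, TFs x subtypes, values in `[0, 1]` or `NA`.
#' @export
motif_enrichment_fraction <- function(specific, hits) {
  tfs <- sort(unique(hits$tf_name))
  out <- matrix(NA_real_, nrow = length(tfs), ncol = length(specific),
                dimnames = list(tfs, names(specific)))
  hit_sets <- split(hits$acr_id, hits$tf_name)
  for (s in names(specific)) {
    ids <- specific[[s]]
    if (length(ids) == 0L) next
    out[, s] <- vapply(tfs, function(tf) {
      mean(ids %in% hit_sets[[tf]])
    }, numeric(1))
  }
  out
}

# One-sided rank-sum test of enriched-subtype samples vs all others, with
# the package-wide fold-change convention (pseudocount on both means).
rank_fc_test <- function(x_in, x_out, pseudocount = 0.01) {
  if (length(x_in) < 2L || length(x_out) < 2L) {
    stop("need at least 2 samples in each group")
  }
  exact <- length(x_in) <= 10L && length(x_out) <= 10L &&
    !anyDuplicated(c(x_in, x_out))
  wt <- suppressWarnings(
    stats::wilcox.test(x_in, x_out, alternative = "greater",
                       exact = exact, correct = TRUE)
  )
  fc <- (mean(x_in) + pseudocount) / (mean(x_out) + pseudocount)
  list(p = wt$p.value, fc = fc)
}

#' Test a TF's expression in its enriched subtype
#'
#' One-sided Wilcoxon rank-sum test (alternative: greater) of the TF's
#' expression in the enriched subtype versus all other samples, a
#' pseudocounted mean fold change, and the expression floor
#' (`log2(FPKM) > min_log2fpkm` in at least one enriched-subtype sample).
#' The TF passes when `p < 0.05`, `fc > fc_thresh` (strict) and the floor is
#' met. The exact rank-sum null is used for group sizes <= 10 without ties,
#' the tie-corrected normal approximation otherwise.
#'
#' @param fpkm expression matrix (genes x samples), FPKM scale.
#' @param labels named character vector, sample id -> subtype.
#' @param tf_name row name of the TF in `fpkm`.
#' @param enriched_subtype subtype whose samples form the test group.
#' @param fc_thresh fold-change threshold (strict `>`).
#' @param min_log2fpkm expression floor on the log2 FPKM scale.
#' @param pseudocount added to both group means before the ratio.
#' @return list with `p`, `fc`, `passes`.
#' @export
tf_expression_test <- function(fpkm, labels, tf_name, enriched_subtype,
                               fc_thresh = 1.2, min_log2fpkm = 1,
                               pseudocount = 0.01) {
  labels <- check_labels(fpkm, labels)
  if (!tf_name %in% rownames(fpkm)) stop("TF '", tf_name, "' not in matrix")
  if (!enriched_subtype %in% labels) {
    stop("subtype '", enriched_subtype, "' absent from labels")
  }
  inside <- labels == enriched_subtype
  x_in <- fpkm[tf_name, inside]
  x_out <- fpkm[tf_name, !inside]
  res <- rank_fc_test(x_in, x_out, pseudocount)
  floor_ok <- any(log2(x_in) > min_log2fpkm)
  list(p = res$p, fc = res$fc,
       passes = res$p < 0.05 && res$fc > fc_thresh && floor_ok)
}

#' Target genes of subtype-specific ACRs (TSS within +/- 1 kb)
#'
#' Genes whose 2-kb TSS window (`[tss - window, tss + window]`, inclusive)
#' overlaps any of the given ACR intervals — the assignment used for TF
#' target-gene aggregation.
#'
#' @param acrs data.frame of ACRs (e.g. the subtype-specific ACRs carrying a
#'   TF's motif).
#' @param genes data.frame of gene models with `tss`.
#' @param window TSS window halfwidth in bp (default 1000).
#' @return character vector of gene ids.
#' @export
tss_window_targets <- function(acrs, genes, window = 1000L) {
  if (nrow(acrs) == 0L || nrow(genes) == 0L) return(character())
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$tss - window),
                    end = genes$tss + window + 1L)
  ov <- intervals_overlap(win, acrs)
  unique(genes$gene_id[ov$query])
}

#' Aggregate target-gene expression evidence for one TF
#'
#' Each target gene gets a one-sided rank-sum p and a pseudocounted log2
#' fold change (enriched subtype vs others) as in [tf_expression_test()].
#' Evidence is aggregated as the geometric mean of the p-values
#' (`exp(mean(log p))`) and the median of the log2 fold changes; the TF is
#' reported significant when the geometric-mean p < 0.05 and the median
#' fold change exceeds 1.2.
#'
#' @param fpkm expression matrix (genes x samples).
#' @param labels named character vector, sample id -> subtype.
#' @param targets character vector of target gene ids (non-empty).
#' @param enriched_subtype subtype whose samples form the test group.
#' @param fc_thresh fold-change threshold on the linear scale.
#' @param pseudocount added to both group means before each ratio.
#' @return list with `target_p` (geometric-mean p), `target_fc` (median
#'   log2 fold change), `n_targets`, `significant`.
#' @export
aggregate_target_genes <- function(fpkm, labels, targets, enriched_subtype,
                                   fc_thresh = 1.2, pseudocount = 0.01) {
  if (length(targets) == 0L) stop("empty target gene list")
  targets <- intersect(targets, rownames(fpkm))
  if (length(targets) == 0L) stop("no target gene has expression data")
  labels <- check_labels(fpkm, labels)
  inside <- labels == enriched_subtype
  if (!any(inside)) stop("subtype '", enriched_subtype, "' absent")
  res <- lapply(targets, function(g) {
    rank_fc_test(fpkm[g, inside], fpkm[g, !inside], pseudocount)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  log2fc <- vapply(res, function(r) log2(r$fc), numeric(1))
  target_p <- exp(mean(log(p)))
  target_fc <- stats::median(log2fc)
  list(target_p = target_p, target_fc = target_fc,
       n_targets = length(targets),
       significant = target_p < 0.05 && 2^target_fc > fc_thresh)
}
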