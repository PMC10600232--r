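# Drug-response analysis: thresholding consumed differential-ACR tables,
# building drug-associated gene sets from expression/AUC correlations across
# cell lines, and Fisher-exact enrichment of differential-ACR target genes.

#' Split a differential-ACR table into relapse-high and relapse-low sets
#'
#' Differential accessibility tables are consumed from an external engine
#' (one row per ACR with `log2fc` and `fdr`). ACRs pass at
#' `|log2fc| > fc_thresh` (strict) and `fdr < fdr_thresh`.
#'
#' @param table data.frame with `acr_id`, `log2fc`, `fdr`.
#' @param fc_thresh log2 fold-change threshold.
#' @param fdr_thresh FDR threshold.
#' @return list with `relapse_high` and `relapse_low` ACR id vectors.
#' @export
filter_differential <- function(table, fc_thresh = 1, fdr_thresh = 0.05) {
  stopifnot(fc_thresh > 0, fdr_thresh > 0)
  sig <- table$fdr < fdr_thresh
  list(
    relapse_high = table$acr_id[sig & table$log2fc > fc_thresh],
    relapse_low = table$acr_id[sig & table$log2fc < -fc_thresh]
  )
}

#' Correlate gene expression with drug response across cell lines
#'
#' Pearson correlation between each gene's expression and each drug's AUC
#' over the shared cell lines, with the two-sided t-test p-value. Pairs with
#' `|r| > r_thresh` (strict) and `p < p_thresh` form the drug-related gene
#' sets; constant vectors are skipped.
#'
#' @param expr gene x cell-line expression matrix.
#' @param auc drug x cell-line AUC matrix.
#' @param r_thresh correlation threshold on `|r|`.
#' @param p_thresh p-value threshold.
#' @return data.frame with `drug`, `gene`, `r`, `p`, `kept`.
#' @export
build_drug_gene_pairs <- function(expr, auc, r_thresh = 0.5,
                                  p_thresh = 0.05) {
  shared <- intersect(colnames(expr), colnames(auc))
  if (length(shared) < 4L) stop("need at least 4 shared cell lines")
  expr <- expr[, shared, drop = FALSE]
  auc <- auc[, shared, drop = FALSE]
  n <- length(shared)
  const_gene <- apply(expr, 1L, stats::sd) == 0
  const_drug <- apply(auc, 1L, stats::sd) == 0
  if (any(const_gene) || any(const_drug)) {
    warning("constant vector(s) skipped: ",
            sum(const_gene), " gene(s), ", sum(const_drug), " drug(s)")
  }
  genes <- rownames(expr)[!const_gene]
  drugs <- rownames(auc)[!const_drug]
  r <- stats::cor(t(auc[drugs, , drop = FALSE]),
                  t(expr[genes, , drop = FALSE]))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(
    drug = rep(drugs, times = length(genes)),
    gene = rep(genes, each = length(drugs)),
    r = as.vector(r), p = as.vector(p),
    stringsAsFactors = FALSE
  )
  out$kept <- abs(out$r) > r_thresh & out$p < p_thresh
  out
}

#' Drug-related gene sets from kept drug-gene pairs
#' @param pairs data.frame from [build_drug_gene_pairs()].
#' @return named list, drug -> character vector of associated genes.
#' @export
drug_gene_sets <- function(pairs) {
  kept <- pairs[pairs$kept, , drop = FALSE]
  split(kept$gene, kept$drug)
}

#' Fisher-exact enrichment of a gene set in a drug-related set
#'
#' 2x2 table of membership in `target_genes` versus membership in
#' `drug_set` over the `background` universe, tested with Fisher's exact
#' test (two-sided by default, so depletion is also detectable).
#'
#' @param target_genes genes of interest (subset of `background`).
#' @param drug_set drug-related gene set (subset of `background`).
#' @param background gene universe, typically all genes entering the
#'   expression/AUC analysis.
#' @param alternative passed to [stats::fisher.test()].
#' @return list with `odds_ratio` (conditional MLE), `p`, and the `table`.
#' @export
enrichment_fisher <- function(target_genes, drug_set, background,
                              alternative = "two.sided") {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background gene universe")
  target_genes <- unique(target_genes)
  drug_set <- unique(drug_set)
  if (length(setdiff(target_genes, background)) ||
      length(setdiff(drug_set, background))) {
    stop("target_genes and drug_set must be subsets of background")
  }
  in_t <- background %in% target_genes
  in_d <- background %in% drug_set
  tab <- matrix(c(sum(in_t & in_d), sum(in_t & !in_d),
                  sum(!in_t & in_d), sum(!in_t & !in_d)),
                nrow = 2L,
                dimnames = list(target = c("in", "out"),
                                drug_set = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
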