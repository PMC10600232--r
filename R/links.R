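# Cis ACR-to-gene association: variance pre-filtering, candidate-pair
# enumeration within a cis window, per-pair standardized regression and
# BH-controlled link calling.

#' Keep the most variable rows of a matrix
#'
#' Rows are ranked by sample variance and the top
#' `ceiling(keep_fraction * nrow)` retained (default: top 75%). Constant
#' rows rank last.
#'
#' @param mat numeric matrix with row names.
#' @param keep_fraction fraction of rows to keep, in `(0, 1]`.
#' @return the retained rows of `mat`, original row order preserved.
#' @export
select_top_variance <- function(mat, keep_fraction = 0.75) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L,
            keep_fraction > 0, keep_fraction <= 1)
  v <- apply(mat, 1L, stats::var)
  k <- ceiling(keep_fraction * nrow(mat))
  keep <- sort(order(-v)[seq_len(k)])
  mat[keep, , drop = FALSE]
}

#' Enumerate candidate cis ACR-gene pairs
#'
#' A pair is a candidate when ACR and gene lie on the same chromosome and
#' the distance between the ACR center and the gene TSS is at most `window`
#' (default 0.5 Mb).
#'
#' @param acrs data.frame of ACRs (`acr_id`, `chrom`, `start`, `end`).
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `tss`).
#' @param window cis window in bp.
#' @return data.frame with `acr_id`, `gene_id`, `distance`.
#' @export
enumerate_cis_pairs <- function(acrs, genes, window = 500000L) {
  stopifnot(window > 0)
  empty <- data.frame(acr_id = character(), gene_id = character(),
                      distance = integer())
  if (nrow(acrs) == 0L || nrow(genes) == 0L) return(empty)
  center <- (acrs$start + acrs$end) %/% 2L
  win <- data.frame(chrom = acrs$chrom,
                    start = pmax(0, center - window),
                    end = center + window + 1L)
  tss_pts <- data.frame(chrom = genes$chrom, start = genes$tss,
                        end = genes$tss + 1L)
  ov <- intervals_overlap(win, tss_pts)
  if (nrow(ov) == 0L) return(empty)
  d <- abs(center[ov$query] - genes$tss[ov$subject])
  keep <- d <= window
  data.frame(acr_id = acrs$acr_id[ov$query][keep],
             gene_id = genes$gene_id[ov$subject][keep],
             distance = as.integer(d[keep]),
             stringsAsFactors = FALSE)
}

#' Fit cis associations and call links
#'
#' For each candidate pair, a simple linear association on z-standardized
#' vectors across shared samples: the slope `beta` equals the sample
#' Pearson correlation, with a two-sided p-value from the t-distribution on
#' `n - 2` df. BH FDR is computed across all tested pairs; a link is kept
#' when `|beta| > beta_thresh` (strict) and `fdr < fdr_thresh`. Pairs with
#' a constant accessibility or expression vector are skipped with a
#' warning.
#'
#' @param pairs data.frame from [enumerate_cis_pairs()].
#' @param acr_mat accessibility matrix (ACRs x samples), e.g. log2 CPM.
#' @param expr_mat expression matrix (genes x samples), same sample set.
#' @param beta_thresh effect-size threshold on `|beta|`.
#' @param fdr_thresh BH FDR threshold.
#' @return data.frame of link records: `acr_id`, `gene_id`, `distance`,
#'   `beta`, `p`, `fdr`, `kept`.
#' @export
fit_and_call_links <- function(pairs, acr_mat, expr_mat, beta_thresh = 0.2,
                               fdr_thresh = 0.05) {
  shared <- intersect(colnames(acr_mat), colnames(expr_mat))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  acr_mat <- acr_mat[, shared, drop = FALSE]
  expr_mat <- expr_mat[, shared, drop = FALSE]
  pairs <- pairs[pairs$acr_id %in% rownames(acr_mat) &
                   pairs$gene_id %in% rownames(expr_mat), , drop = FALSE]
  n <- length(shared)
  x <- acr_mat[pairs$acr_id, , drop = FALSE]
  y <- expr_mat[pairs$gene_id, , drop = FALSE]
  sx <- apply(x, 1L, stats::sd)
  sy <- apply(y, 1L, stats::sd)
  const <- sx == 0 | sy == 0
  if (any(const)) {
    warning(sum(const), " pair(s) with a constant vector skipped")
  }
  beta <- rep(NA_real_, nrow(pairs))
  ok <- which(!const)
  if (length(ok)) {
    xc <- x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])
    yc <- y[ok, , drop = FALSE] - rowMeans(y[ok, , drop = FALSE])
    beta[ok] <- rowSums(xc * yc) /
      sqrt(rowSums(xc^2) * rowSums(yc^2))
  }
  tstat <- beta * sqrt((n - 2) / pmax(1 - beta^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- pairs
  out$beta <- beta
  out$p <- p
  out <- out[!const, , drop = FALSE]
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$kept <- abs(out$beta) > beta_thresh & out$fdr < fdr_thresh
  rownames(out) <- NULL
  out
}
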