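# Hierarchical ACR landscape construction: summit extension, per-sample
# score-per-million normalization, greedy significance-ranked overlap
# resolution, and sample -> patient -> cohort merging; plus CPM
# quantification and the recurrence filter.

LEVELS <- c("sample", "patient", "cohort")

next_level <- function(level) {
  i <- match(level, LEVELS)
  if (is.na(i)) stop("unknown ACR level: ", level)
  LEVELS[min(i + 1L, length(LEVELS))]
}

#' Extend peak summits into fixed-width ACRs
#'
#' Each peak summit is extended `halfwidth` bp up- and downstream, producing
#' an accessible chromatin region of width `2 * halfwidth + 1` (501 bp at the
#' default) carrying the peak's significance score (-log10 p). Windows that
#' would extend past position 0 are clamped at 0 and flagged `truncated`
#' rather than dropped.
#'
#' @param peaks data.frame of peaks as from [read_narrowpeak()] (`chrom`,
#'   `summit`, `score`, `sample_id`).
#' @param halfwidth extension in bp on each side of the summit (default 250).
#' @return data.frame of sample-level ACRs: `acr_id`, `chrom`, `start`,
#'   `end`, `summit`, `score`, `level`, `source_sample`, `truncated`.
#' @examples
#' p <- data.frame(chrom = "chr1", start = 900L, end = 1101L, summit = 1000L,
#'                 score = 10, sample_id = "s1")
#' summit_to_acr(p)  # [750, 1251), width 501
#' @export
summit_to_acr <- function(peaks, halfwidth = 250L) {
  stopifnot(halfwidth >= 0, all(peaks$summit >= 0))
  start <- peaks$summit - as.integer(halfwidth)
  truncated <- start < 0L
  start[truncated] <- 0L
  end <- peaks$summit + as.integer(halfwidth) + 1L
  acrs <- data.frame(
    acr_id = make.unique(sprintf("%s:%d-%d", peaks$chrom, start, end),
                         sep = "_"),
    chrom = peaks$chrom, start = start, end = end,
    summit = peaks$summit, score = peaks$score,
    level = "sample", source_sample = peaks$sample_id,
    truncated = truncated, stringsAsFactors = FALSE
  )
  if (nrow(acrs)) check_intervals(acrs, "ACR")
  acrs
}

#' Greedy significance-ranked overlap resolution
#'
#' Implements the iterative-removal rule used at every merge level: regions
#' are sorted by decreasing score and visited in order; each retained region
#' removes every not-yet-retained region that overlaps it (>= 1 shared base,
#' half-open). Ties on the score are broken by ascending (`chrom`, `start`)
#' so results are deterministic. The output is pairwise non-overlapping and
#' the operation is idempotent.
#'
#' @param acrs data.frame of ACRs.
#' @param key scoring column: `"score"` (raw -log10 p) or `"norm_score"`.
#' @return the retained rows, ordered by (`chrom`, `start`).
#' @export
select_nonoverlapping <- function(acrs, key = c("score", "norm_score")) {
  key <- match.arg(key)
  if (!key %in% names(acrs)) stop("column '", key, "' missing")
  n <- nrow(acrs)
  if (n <= 1L) return(acrs)
  check_intervals(acrs, "ACR")
  ord <- order(-acrs[[key]], as.character(acrs$chrom), acrs$start)
  gr <- as_granges(acrs)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  # self-hits guarantee every index appears as a query, so the split is dense
  adj <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    blocked[adj[[i]]] <- TRUE
  }
  out <- acrs[keep, , drop = FALSE]
  out[order(as.character(out$chrom), out$start), , drop = FALSE]
}

#' Score-per-million normalization of one sample's ACR scores
#'
#' Rescales the significance scores of one ACR set so they sum to one
#' million (`norm_score_i = score_i * 1e6 / sum(score)`), making scores
#' comparable across samples with different peak-calling depth before sets
#' are merged.
#'
#' @param acrs non-empty data.frame of ACRs for a single sample with a
#'   positive total `score`.
#' @return `acrs` with a `norm_score` column summing to 1e6.
#' @export
normalize_score_per_million <- function(acrs) {
  if (nrow(acrs) == 0L) stop("cannot normalize an empty ACR set")
  total <- sum(acrs$score)
  if (!is.finite(total) || total <= 0) {
    stop("total ACR score must be positive for score-per-million")
  }
  acrs$norm_score <- acrs$score * 1e6 / total
  acrs
}

is_normalized <- function(acrs, tol = 1e-6) {
  "norm_score" %in% names(acrs) &&
    abs(sum(acrs$norm_score) - 1e6) <= 1e6 * tol
}

#' Merge normalized ACR sets into the next hierarchy level
#'
#' Pools two or more score-per-million-normalized, internally
#' non-overlapping ACR sets and resolves overlaps greedily by the normalized
#' score ([select_nonoverlapping()]). A single input set (e.g. a
#' diagnosis-only or relapse-only patient) passes through unchanged except
#' for the promoted level. Sets whose `norm_score` does not sum to 1e6 are
#' rejected.
#'
#' @param sets list of ACR data.frames, each already normalized.
#' @param level level of the output; defaults to the successor of the
#'   inputs' level (sample -> patient -> cohort).
#' @return data.frame of merged, pairwise non-overlapping ACRs.
#' @export
merge_acr_sets <- function(sets, level = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  for (i in seq_along(sets)) {
    if (!is_normalized(sets[[i]])) {
      stop("input set ", i, " is not score-per-million normalized")
    }
  }
  if (is.null(level)) {
    level <- if (is.null(sets[[1L]]$level)) "patient"
             else next_level(sets[[1L]]$level[1L])
  }
  if (length(sets) == 1L) {
    out <- sets[[1L]]
  } else {
    pooled <- do.call(rbind, sets)
    out <- select_nonoverlapping(pooled, key = "norm_score")
  }
  out$level <- level
  out
}

#' Build the cohort-level ACR set from per-sample peaks
#'
#' Runs the full merge hierarchy: per sample, summits are extended
#' ([summit_to_acr()]), overlaps resolved by raw significance
#' ([select_nonoverlapping()]) and scores normalized to score-per-million;
#' each patient's sample sets are merged (single-sample patients pass
#' through), re-normalized on the normalized scale, and all patient sets are
#' pooled into the cohort-level set by one final greedy selection on the
#' normalized scores.
#'
#' @param peaks data.frame of peaks for all samples (with `sample_id`).
#' @param sample_patients named character vector, sample id -> patient id.
#' @param halfwidth summit extension in bp.
#' @return data.frame of cohort-level, pairwise non-overlapping ACRs.
#' @export
build_cohort_acrs <- function(peaks, sample_patients, halfwidth = 250L) {
  by_sample <- split(peaks, peaks$sample_id)
  miss <- setdiff(names(by_sample), names(sample_patients))
  if (length(miss)) stop("no patient for sample(s): ",
                         paste(miss, collapse = ", "))
  sample_sets <- lapply(by_sample, function(p) {
    acrs <- summit_to_acr(p, halfwidth)
    acrs <- select_nonoverlapping(acrs, key = "score")
    normalize_score_per_million(acrs)
  })
  by_patient <- split(names(sample_sets),
                      sample_patients[names(sample_sets)])
  patient_sets <- lapply(by_patient, function(ids) {
    merged <- merge_acr_sets(sample_sets[ids])
    merged$score <- merged$norm_score  # re-normalize on the normalized scale
    normalize_score_per_million(merged)
  })
  merge_acr_sets(unname(patient_sets), level = "cohort")
}

#' Counts-per-million normalization of an ACR count matrix
#'
#' `cpm[i, j] = counts[i, j] * 1e6 / sum(counts[, j])`; every column of the
#' result sums to one million.
#'
#' @param counts non-negative integer matrix, ACRs in rows, samples in
#'   columns, with dimnames.
#' @return numeric CPM matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0][1L]
    stop("zero-total count column for sample '", bad, "'")
  }
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Recurrence filter on a CPM matrix
#'
#' Retains ACRs whose `log2(CPM)` exceeds `min_log2cpm` in at least
#' `min_samples` samples (defaults: `log2(CPM) > 0` in >= 2 samples).
#' `log2(0)` is `-Inf` and never passes.
#'
#' @param cpm CPM matrix from [compute_cpm()].
#' @param min_log2cpm log2 CPM threshold (strict `>`).
#' @param min_samples minimum number of samples above threshold.
#' @return character vector of retained ACR row names.
#' @export
filter_recurrent <- function(cpm, min_log2cpm = 0, min_samples = 2L) {
  stopifnot(is.finite(min_log2cpm), min_samples >= 0)
  above <- log2(cpm) > min_log2cpm
  rownames(cpm)[rowSums(above) >= min_samples]
}
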