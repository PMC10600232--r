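# Relapse-free-survival screening: per-ACR median-CPM dichotomization,
# two-group log-rank testing and BH FDR control across the landscape.

#' Median split of a per-sample CPM row
#'
#' Samples with value strictly above the median form the high group; values
#' at or below the median (including ties at the median) go low. If all
#' values are equal the high group is empty and the ACR is skipped by the
#' screen.
#'
#' @param values named numeric vector (names = sample ids), length >= 4.
#' @return list with `high` and `low` sample-id vectors.
#' @export
median_split <- function(values) {
  if (length(values) < 4L) stop("median split needs at least 4 samples")
  if (is.null(names(values))) stop("values must be named by sample id")
  med <- stats::median(values)
  list(high = names(values)[values > med],
       low = names(values)[values <= med])
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (observed minus expected events over the
#' pooled risk sets) with a chi-square p-value on 1 df, plus the direction
#' flag `high_group_worse` (more observed than expected events in the high
#' group).
#'
#' @param high,low sample-id vectors of the two groups (both non-empty).
#' @param surv data.frame with `sample_id`, `time` (> 0), `event`
#'   (1 = relapse, 0 = censored); must cover every sample and have at
#'   least one event overall.
#' @return list with `chi_sq`, `p`, `high_group_worse`.
#' @export
logrank_test <- function(high, low, surv) {
  if (length(high) == 0L || length(low) == 0L) {
    stop("both groups must be non-empty")
  }
  ids <- c(high, low)
  i <- match(ids, surv$sample_id)
  if (anyNA(i)) stop("missing survival record for sample ",
                     ids[is.na(i)][1L])
  time <- surv$time[i]
  event <- surv$event[i]
  if (any(time <= 0)) stop("survival times must be positive")
  if (sum(event) < 1L) stop("need at least one event")
  grp <- factor(rep(c("high", "low"), c(length(high), length(low))),
                levels = c("high", "low"))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi_sq <- unname(sd_fit$chisq)
  list(chi_sq = chi_sq,
       p = stats::pchisq(chi_sq, df = 1L, lower.tail = FALSE),
       high_group_worse = unname(sd_fit$obs[1L] > sd_fit$exp[1L]))
}

#' Screen ACRs for association with relapse-free survival
#'
#' For every ACR row: median-CPM split of the samples, log-rank test
#' between the high and low groups, then BH FDR across all tested ACRs.
#' Degenerate splits (empty high group, e.g. a constant row) are skipped
#' and reported with a reason. The RFS-related set is `fdr < fdr_thresh`.
#'
#' @param cpm CPM matrix restricted to the relapse samples (one column per
#'   patient).
#' @param surv survival table covering every column of `cpm`.
#' @param fdr_thresh BH FDR threshold for the `rfs_related` flag.
#' @return data.frame with one row per ACR: `acr_id`, `chi_sq`, `p`, `fdr`,
#'   `high_group_worse`, `skipped`, `reason`, `rfs_related`.
#' @export
screen_rfs_acrs <- function(cpm, surv, fdr_thresh = 0.05) {
  stopifnot(is.matrix(cpm))
  miss <- setdiff(colnames(cpm), surv$sample_id)
  if (length(miss)) stop("no survival record for sample(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(cpm)
  chi_sq <- p <- rep(NA_real_, n)
  worse <- rep(NA, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    row <- cpm[i, ]
    split <- median_split(row)
    if (length(split$high) == 0L) {
      reason[i] <- "degenerate median split"
      next
    }
    lr <- logrank_test(split$high, split$low, surv)
    chi_sq[i] <- lr$chi_sq
    p[i] <- lr$p
    worse[i] <- lr$high_group_worse
  }
  fdr <- rep(NA_real_, n)
  tested <- !is.na(p)
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(
    acr_id = rownames(cpm), chi_sq = chi_sq, p = p, fdr = fdr,
    high_group_worse = worse, skipped = !tested, reason = reason,
    rfs_related = !is.na(fdr) & fdr < fdr_thresh,
    stringsAsFactors = FALSE
  )
}
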