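# Independent oracles used across the suite. Each re-derives the expected
# result by brute force or closed form, never by calling the code path it
# checks.

# O(n^2) greedy overlap-removal oracle: sort by decreasing key (ties by
# chrom then start), scan, keep an element iff it overlaps no kept element.
oracle_greedy_select <- function(df, key) {
  ord <- order(-df[[key]], as.character(df$chrom), df$start)
  kept <- integer()
  for (i in ord) {
    hit <- FALSE
    for (j in kept) {
      if (df$chrom[i] == df$chrom[j] &&
          min(df$end[i], df$end[j]) > max(df$start[i], df$start[j])) {
        hit <- TRUE
        break
      }
    }
    if (!hit) kept <- c(kept, i)
  }
  sort(kept)
}

# quadratic all-vs-all overlap scan
oracle_overlap_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov > 0) out <- rbind(out, c(i, j, ov))
    }
  }
  if (is.null(out)) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  }
  data.frame(query = out[, 1], subject = out[, 2], overlap = out[, 3])
}

random_acr_set <- function(n, chroms = c("c1", "c2"), max_pos = 2000,
                           width_range = c(50, 400)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  data.frame(
    acr_id = paste0("r", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    score = round(stats::runif(n, 0.1, 50), 3),
    level = "sample",
    stringsAsFactors = FALSE
  )
}

# textbook BH step-up: adjusted p_(i) = min_{j >= i} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-group log-rank by explicit risk-set tabulation
oracle_logrank <- function(time, event, in_group1) {
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_sq = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE),
       O = O, E = E)
}

# exhaustive two-sided Fisher p: sum of hypergeometric probabilities of
# tables (with the same margins) no more likely than the observed one
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ])   # targets
  m2 <- sum(tab[2, ])
  k <- sum(tab[, 1])    # drug-set column total
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact one-sided rank-sum p (alternative: first group greater) by
# enumeration of all group assignments
oracle_ranksum_greater <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  r_all <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mean(r_all >= r_obs)
}

# p-value of a Pearson correlation from the closed-form t transform
oracle_cor_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# construct y with an exact given sample correlation to x
make_cor_exactly <- function(x, rho, helper) {
  zx <- as.vector(scale(x))
  h <- helper - mean(helper)
  h <- h - zx * sum(h * zx) / sum(zx^2)   # orthogonalize
  zh <- h / stats::sd(h)
  rho * zx + sqrt(1 - rho^2) * zh
}
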