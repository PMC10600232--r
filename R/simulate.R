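# Seeded synthetic-cohort generators with planted ground truth. The
# generators emulate the statistical structure the analysis assumes --
# summit-scored peak sets, negative-binomial count matrices with subtype
# structure, binomial allelic reads with planted imbalance, expression
# linearly coupled to planted ACRs, exponential survival coupled to ACR
# groups, and drug AUC vectors correlated with planted genes -- so every
# stage of the pipeline can be exercised against known truth.
#
# One seeded stream per data domain (loci, counts, peaks, genes/expression,
# alleles, survival, drugs): enabling one component never shifts another's
# draws.

#' Configuration of the synthetic cohort
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 24 samples in 4 subtypes (6 per subtype), 2000 accessible loci on
#' a 2 x 20 Mb toy genome, negative-binomial counts (size 10) at ~1e7
#' fragments per sample with ~20 high-signal loci carrying 99.8% of the
#' library so study loci sit at CPM of order 1 (the regime in which the
#' absolute CPM thresholds are meaningful), 4-fold subtype effects, planted
#' cis links at correlation 0.6, allelic imbalance at true alt fraction
#' 0.85 with ATAC coverage 30-200, and a 42-sample relapse set with hazard
#' ratio 4 for the planted risk group.
#'
#' @param n_samples number of cohort samples.
#' @param n_subtypes number of molecular subtypes (samples assigned per
#'   patient, round-robin).
#' @param n_acrs number of study loci (excluding high-signal loci).
#' @param genome data.frame with `chrom`, `length` (bp).
#' @param fraction_subtype_specific fraction of study loci planted with a
#'   subtype effect.
#' @param subtype_effect multiplicative CPM shift in the target subtype.
#' @param n_planted_links number of planted cis ACR-gene links.
#' @param link_correlation true correlation of planted links.
#' @param n_planted_asoc number of loci planted with allelic imbalance.
#' @param asoc_true_af true ATAC alt-allele fraction at planted loci
#'   (in (0, 1); balanced loci use 0.5).
#' @param snp_coverage_range ATAC coverage range at simulated SNPs.
#' @param n_planted_risk_acrs loci coupled to relapse-free survival.
#' @param risk_hazard_ratio hazard multiplier for the planted risk group.
#' @param n_survival_samples number of relapse samples in the survival set.
#' @param censoring_rate approximate fraction of censored samples
#'   (1 = everyone censored).
#' @param n_genes number of gene models in the cohort.
#' @param n_cell_lines,n_drugs,n_drug_genes,n_drug_expr_genes,drug_correlation
#'   drug-response block: cell lines, drugs, planted drug-associated genes,
#'   total genes in the cell-line expression matrix, and the true
#'   expression-AUC correlation of planted genes.
#' @param nb_size negative-binomial size (dispersion) of the counts.
#' @param depth mean per-sample library size (fragments).
#' @param n_highsignal number of high-signal loci.
#' @param background_fraction fraction of the library absorbed by
#'   high-signal loci.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 24L, n_subtypes = 4L, n_acrs = 2000L,
                       genome = data.frame(chrom = c("chrA", "chrB"),
                                           length = c(2e7, 2e7)),
                       fraction_subtype_specific = 0.05,
                       subtype_effect = 4,
                       n_planted_links = 50L, link_correlation = 0.6,
                       n_planted_asoc = 50L, asoc_true_af = 0.85,
                       snp_coverage_range = c(30L, 200L),
                       n_planted_risk_acrs = 4L, risk_hazard_ratio = 4,
                       n_survival_samples = 42L, censoring_rate = 0.1,
                       n_genes = 600L,
                       n_cell_lines = 11L, n_drugs = 8L,
                       n_drug_genes = 24L, n_drug_expr_genes = 300L,
                       drug_correlation = 0.8,
                       nb_size = 10, depth = 1e7,
                       n_highsignal = 20L, background_fraction = 0.998,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_subtypes = as.integer(n_subtypes),
    n_acrs = as.integer(n_acrs), genome = genome,
    fraction_subtype_specific = fraction_subtype_specific,
    subtype_effect = subtype_effect,
    n_planted_links = as.integer(n_planted_links),
    link_correlation = link_correlation,
    n_planted_asoc = as.integer(n_planted_asoc),
    asoc_true_af = asoc_true_af,
    snp_coverage_range = as.integer(snp_coverage_range),
    n_planted_risk_acrs = as.integer(n_planted_risk_acrs),
    risk_hazard_ratio = risk_hazard_ratio,
    n_survival_samples = as.integer(n_survival_samples),
    censoring_rate = censoring_rate,
    n_genes = as.integer(n_genes),
    n_cell_lines = as.integer(n_cell_lines), n_drugs = as.integer(n_drugs),
    n_drug_genes = as.integer(n_drug_genes),
    n_drug_expr_genes = as.integer(n_drug_expr_genes),
    drug_correlation = drug_correlation,
    nb_size = nb_size, depth = depth,
    n_highsignal = as.integer(n_highsignal),
    background_fraction = background_fraction,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_samples >= 0, n_subtypes >= 1, n_acrs >= 0,
      fraction_subtype_specific >= 0, fraction_subtype_specific <= 1,
      subtype_effect > 0, n_planted_links >= 0,
      link_correlation >= -1, link_correlation <= 1,
      n_planted_asoc >= 0, asoc_true_af > 0, asoc_true_af < 1,
      length(snp_coverage_range) == 2L,
      snp_coverage_range[1] >= 1, diff(snp_coverage_range) >= 0,
      n_planted_risk_acrs >= 0, risk_hazard_ratio > 0,
      censoring_rate >= 0, censoring_rate <= 1,
      nb_size > 0, depth > 0, n_highsignal >= 0,
      background_fraction >= 0, background_fraction < 1
    )
  })
  structure(cfg, class = "sim_config")
}

# Non-overlapping 501-bp loci on a 1-kb grid (each locus, even after
# +/-100 bp summit jitter, stays inside its own slot).
place_loci <- function(genome, n, prefix = "acr") {
  slots_per_chrom <- pmax(0L, as.integer(genome$length %/% 1000L) - 1L)
  total <- sum(slots_per_chrom)
  if (total < n) {
    stop("genome too small for ", n, " non-overlapping loci (",
         total, " slots)")
  }
  if (n == 0L) {
    return(data.frame(acr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      summit = integer(), stringsAsFactors = FALSE))
  }
  picked <- sort(sample.int(total, n))
  chrom_idx <- findInterval(picked - 1L, cumsum(c(0L, slots_per_chrom)),
                            rightmost.closed = FALSE)
  offset <- picked - c(0L, cumsum(slots_per_chrom))[chrom_idx]
  summit <- offset * 1000L + 500L
  data.frame(
    acr_id = sprintf("%s%04d", prefix, seq_len(n)),
    chrom = as.character(genome$chrom[chrom_idx]),
    start = summit - 250L, end = summit + 251L, summit = summit,
    stringsAsFactors = FALSE
  )
}

# NB counts for given relative locus weights and per-sample shift matrix.
sim_counts <- function(weights, shift, depth, nb_size, acr_ids,
                       sample_ids) {
  m <- length(sample_ids)
  depth_j <- stats::runif(m, 0.8, 1.2) * depth
  w <- weights * shift                       # loci x samples
  w <- sweep(w, 2L, colSums(w), "/")
  mu <- sweep(w, 2L, depth_j, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size),
                   nrow = nrow(mu),
                   dimnames = list(acr_ids, sample_ids))
  counts
}

#' Simulate a synthetic ATAC-seq cohort with planted ground truth
#'
#' Generates per-sample peak sets (summits jittered around fixed loci,
#' scores derived from counts), a negative-binomial count matrix with
#' per-sample library sizes, subtype labels (per patient; an odd cohort
#' size leaves the last patient diagnosis-only), gene models, an expression
#' matrix with genes linearly coupled to planted ACRs, and the ground
#' truth. Deterministic for a fixed seed.
#'
#' Planted subtype-specific loci sit just below the accessibility threshold
#' outside their subtype and are shifted `subtype_effect`-fold inside it;
#' planted link genes are coupled to the realized log2 CPM of their ACR at
#' `link_correlation`.
#'
#' @param config a [sim_config()].
#' @return list with `acrs` (all loci), `peaks`, `counts`, `labels`
#'   (data.frame), `subtypes` (named vector for `call_subtype_specific()`),
#'   `genes`, `fpkm`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_acrs + config$n_highsignal
  m <- config$n_samples

  set.seed(config$seed + 11L)
  loci <- place_loci(config$genome, n_total)
  is_high <- seq_len(n_total) > config$n_acrs
  loci$is_highsignal <- is_high

  # patients and subtype labels (two samples per patient, D then R)
  n_patients <- ceiling(m / 2)
  patient <- rep(seq_len(n_patients), each = 2L)[seq_len(m)]
  phase <- rep(c("diagnosis", "relapse"), length.out = 2L * n_patients)[
    seq_len(m)]
  subtype <- paste0("S", ((patient - 1L) %% config$n_subtypes) + 1L)
  sample_ids <- sprintf("s%02d", seq_len(m))
  labels <- data.frame(sample_id = sample_ids,
                       patient_id = sprintf("p%02d", patient),
                       phase = phase, subtype = subtype,
                       stringsAsFactors = FALSE)
  subtypes <- stats::setNames(subtype, sample_ids)

  n_spec <- round(config$fraction_subtype_specific * config$n_acrs)
  spec_idx <- if (n_spec > 0) sample.int(config$n_acrs, n_spec)
              else integer()
  spec_subtype <- rep(paste0("S", seq_len(config$n_subtypes)),
                      length.out = n_spec)

  set.seed(config$seed + 23L)
  rel <- numeric(n_total)
  rel[!is_high] <- stats::rlnorm(config$n_acrs, log(1.0), 0.7)
  # planted loci: narrow band just below the calling threshold (~0.85 CPM),
  # so the multiplicative subtype effect carries them across it
  rel[spec_idx] <- stats::rlnorm(n_spec, log(1.1), 0.05)
  w_study <- rel[!is_high]
  weights <- numeric(n_total)
  weights[!is_high] <- w_study / sum(w_study) *
    (1 - config$background_fraction)
  if (config$n_highsignal > 0) {
    weights[is_high] <- config$background_fraction / config$n_highsignal
  }
  shift <- matrix(1, nrow = n_total, ncol = m)
  if (n_spec > 0) {
    for (k in seq_len(n_spec)) {
      shift[spec_idx[k], subtypes == spec_subtype[k]] <-
        config$subtype_effect
    }
  }
  counts <- sim_counts(weights, shift, config$depth, config$nb_size,
                       loci$acr_id, sample_ids)

  set.seed(config$seed + 37L)
  jitter <- matrix(sample(-100:100, n_total * m, replace = TRUE),
                   nrow = n_total)
  score <- log1p(counts) * 3 +
    matrix(stats::runif(n_total * m, 0, 0.5), nrow = n_total)
  peaks <- data.frame(
    chrom = rep(loci$chrom, times = m),
    start = rep(loci$summit, m) + as.vector(jitter) - 250L,
    end = rep(loci$summit, m) + as.vector(jitter) + 251L,
    name = paste0(rep(loci$acr_id, m), "_", rep(sample_ids, each = n_total)),
    summit = rep(loci$summit, m) + as.vector(jitter),
    score = round(pmax(as.vector(score), 0.01), 4),
    sample_id = rep(sample_ids, each = n_total),
    stringsAsFactors = FALSE
  )

  set.seed(config$seed + 53L)
  cpm <- compute_cpm(counts)
  genes <- sim_genes(config, loci, spec_idx, spec_subtype)
  fpkm <- sim_expression(config, genes, cpm, subtypes)

  truth <- list(
    subtype_specific = split(loci$acr_id[spec_idx], spec_subtype),
    links = genes$truth_links,
    subtype_targets = genes$truth_targets,
    highsignal_acrs = loci$acr_id[is_high]
  )
  list(acrs = loci, peaks = peaks, counts = counts, labels = labels,
       subtypes = subtypes, genes = genes$models, fpkm = fpkm,
       truth = truth, config = config)
}

# Gene models: planted-link genes near candidate ACRs, promoter-proximal
# target genes inside planted subtype ACRs, and null genes.
sim_genes <- function(config, loci, spec_idx, spec_subtype) {
  study_idx <- which(!loci$is_highsignal)
  candidates <- setdiff(study_idx, spec_idx)
  n_links <- min(config$n_planted_links, length(candidates))
  link_acr <- sample(candidates, n_links)
  link_tss <- loci$summit[link_acr] +
    round(stats::runif(n_links, -1, 1) * 4e5)
  chrom_len <- stats::setNames(config$genome$length, config$genome$chrom)
  link_chrom <- loci$chrom[link_acr]
  link_tss <- pmax(1000L, pmin(as.integer(chrom_len[link_chrom]) - 6000L,
                               link_tss))

  n_tgt_per <- 2L
  tgt_rows <- integer()
  tgt_subtype <- character()
  for (s in unique(spec_subtype)) {
    pool <- spec_idx[spec_subtype == s]
    take <- head(pool, n_tgt_per)
    tgt_rows <- c(tgt_rows, take)
    tgt_subtype <- c(tgt_subtype, rep(s, length(take)))
  }
  tgt_tss <- loci$summit[tgt_rows]
  tgt_chrom <- loci$chrom[tgt_rows]

  n_used <- n_links + length(tgt_rows)
  n_null <- max(0L, config$n_genes - n_used)
  null_chrom_i <- sample.int(nrow(config$genome), n_null, replace = TRUE)
  null_chrom <- as.character(config$genome$chrom[null_chrom_i])
  null_tss <- vapply(null_chrom_i, function(i) {
    round(stats::runif(1, 1e4, config$genome$length[i] - 1e4))
  }, numeric(1))

  chrom <- c(link_chrom, tgt_chrom, null_chrom)
  tss <- as.integer(c(link_tss, tgt_tss, null_tss))
  n_genes <- length(tss)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  len <- 5000L
  strand[tss < len] <- "+"  # keep minus-strand gene bodies on the contig
  start <- ifelse(strand == "+", tss, tss - len + 1L)
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  models <- gene_models(data.frame(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + len), strand = strand, gene_id = gene_id,
    cosmic = stats::runif(n_genes) < 0.1,
    stringsAsFactors = FALSE
  ))
  stopifnot(all(models$tss == tss))
  list(
    models = models,
    truth_links = data.frame(
      acr_id = loci$acr_id[link_acr],
      gene_id = gene_id[seq_len(n_links)],
      correlation = rep(config$link_correlation, n_links),
      stringsAsFactors = FALSE
    ),
    truth_targets = data.frame(
      subtype = tgt_subtype,
      acr_id = loci$acr_id[tgt_rows],
      gene_id = gene_id[n_links + seq_along(tgt_rows)],
      stringsAsFactors = FALSE
    )
  )
}

sim_expression <- function(config, genes, cpm, subtypes) {
  models <- genes$models
  m <- ncol(cpm)
  fpkm <- matrix(stats::rlnorm(nrow(models) * m, log(5), 0.8),
                 nrow = nrow(models),
                 dimnames = list(models$gene_id, colnames(cpm)))
  r <- config$link_correlation
  links <- genes$truth_links
  for (k in seq_len(nrow(links))) {
    x <- log2(cpm[links$acr_id[k], ] + 1)
    if (stats::sd(x) == 0) next
    z <- (x - mean(x)) / stats::sd(x)
    e <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(m)
    fpkm[links$gene_id[k], ] <- pmax(0.01, 8 + 2 * e)
  }
  tgt <- genes$truth_targets
  for (k in seq_len(nrow(tgt))) {
    base <- stats::rlnorm(m, log(5), 0.3)
    fpkm[tgt$gene_id[k], ] <-
      base * ifelse(subtypes == tgt$subtype[k], 3, 1)
  }
  fpkm
}

#' Simulate heterozygous-SNP allelic reads with planted imbalance
#'
#' Places 1-3 heterozygous SNPs inside each of `n_acrs` loci. WGS counts
#' are binomial at allele fraction 0.5 (depth ~ 10 + Poisson(30)); ATAC
#' counts are binomial at fraction 0.5 for balanced loci and at
#' `asoc_true_af` (randomly toward the ref or alt allele) for the
#' `n_planted_asoc` planted loci, with coverage drawn uniformly from
#' `snp_coverage_range`. With `n_acrs = 0` the output is empty.
#'
#' @param config a [sim_config()].
#' @return list with `snps` (allelic records, 0-based positions), `acrs`,
#'   and `truth` (`asoc_acr_ids`, named `true_af`).
#' @export
simulate_allelic_reads <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 67L)
  if (config$n_acrs == 0L) {
    acrs <- place_loci(config$genome, 0L)
    return(list(
      snps = data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        wgs_ref = integer(), wgs_alt = integer(),
                        atac_ref = integer(), atac_alt = integer(),
                        sample_id = character()),
      acrs = acrs,
      truth = list(asoc_acr_ids = character(), true_af = numeric())
    ))
  }
  acrs <- place_loci(config$genome, config$n_acrs)
  n_planted <- min(config$n_planted_asoc, config$n_acrs)
  planted <- if (n_planted > 0) sample.int(config$n_acrs, n_planted)
             else integer()
  true_af <- rep(0.5, config$n_acrs)
  if (n_planted > 0) {
    toward_alt <- stats::runif(n_planted) < 0.5
    true_af[planted] <- ifelse(toward_alt, config$asoc_true_af,
                               1 - config$asoc_true_af)
  }
  n_snps <- sample(1:3, config$n_acrs, replace = TRUE)
  acr_of <- rep(seq_len(config$n_acrs), n_snps)
  pos <- acrs$start[acr_of] +
    unlist(lapply(n_snps, function(k) sample(10:490, k)))
  total <- length(acr_of)
  wgs_depth <- 10L + stats::rpois(total, 30)
  wgs_alt <- stats::rbinom(total, wgs_depth, 0.5)
  N <- sample(seq(config$snp_coverage_range[1],
                  config$snp_coverage_range[2]), total, replace = TRUE)
  atac_alt <- stats::rbinom(total, N, true_af[acr_of])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                character(1))
  snps <- data.frame(
    chrom = acrs$chrom[acr_of], pos = as.integer(pos),
    ref = ref, alt = unname(alt),
    wgs_ref = wgs_depth - wgs_alt, wgs_alt = wgs_alt,
    atac_ref = N - atac_alt, atac_alt = atac_alt,
    sample_id = "s1", stringsAsFactors = FALSE
  )
  rownames(snps) <- NULL
  list(snps = snps, acrs = acrs,
       truth = list(asoc_acr_ids = acrs$acr_id[planted],
                    true_af = stats::setNames(true_af, acrs$acr_id)))
}

#' Simulate survival, drug-response and differential-accessibility data
#'
#' Builds (1) a relapse-sample CPM matrix with `n_planted_risk_acrs` loci
#' strongly elevated in a planted risk group, exponential relapse-free
#' survival times whose hazard is multiplied by `risk_hazard_ratio` for the
#' risk group, and independent censoring (`censoring_rate = 1` censors
#' everyone); (2) a cell-line expression matrix and drug AUC matrix with
#' planted drug-associated genes at correlation `drug_correlation`; (3) a
#' consumed-style differential-ACR table derived from simulated
#' diagnosis/relapse shifts (Welch t on log2 CPM, BH), plus an ACR-to-gene
#' map in which planted relapse-high ACRs preferentially target planted
#' drug genes.
#'
#' @param config a [sim_config()].
#' @return list with `survival`, `cpm`, `risk_group`, `diff_table`,
#'   `acr_gene_map`, `expr`, `auc`, `truth`, `config`.
#' @export
simulate_survival_and_drug <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 79L)
  n <- config$n_survival_samples
  sample_ids <- sprintf("r%02d", seq_len(n))
  n_total <- config$n_acrs + config$n_highsignal
  rel <- numeric(n_total)
  rel[seq_len(config$n_acrs)] <- stats::rlnorm(config$n_acrs, log(1), 0.7)
  # planted diagnosis/relapse differential loci get a moderate baseline so
  # a 4-fold shift is expressible on the CPM scale in both directions
  n_planted_diff <- min(30L, config$n_acrs)
  diff_planted <- if (n_planted_diff > 0)
    sample.int(config$n_acrs, n_planted_diff) else integer()
  rel[diff_planted] <- stats::rlnorm(n_planted_diff, log(1.5), 0.2)
  weights <- numeric(n_total)
  weights[seq_len(config$n_acrs)] <- rel[seq_len(config$n_acrs)] /
    sum(rel[seq_len(config$n_acrs)]) * (1 - config$background_fraction)
  if (config$n_highsignal > 0) {
    weights[config$n_acrs + seq_len(config$n_highsignal)] <-
      config$background_fraction / config$n_highsignal
  }
  acr_ids <- c(sprintf("acr%04d", seq_len(config$n_acrs)),
               sprintf("hs%03d", seq_len(config$n_highsignal)))

  risk_group <- sort(sample(sample_ids, floor(n / 2)))
  n_risk_acrs <- min(config$n_planted_risk_acrs, config$n_acrs)
  risk_idx <- if (n_risk_acrs > 0) sample.int(config$n_acrs, n_risk_acrs)
              else integer()
  shift <- matrix(1, nrow = n_total, ncol = n)
  shift[risk_idx, sample_ids %in% risk_group] <- 6  # clear median split
  counts <- sim_counts(weights, shift, config$depth, config$nb_size,
                       acr_ids, sample_ids)
  cpm <- compute_cpm(counts)

  # exponential RFS, baseline median 24 months, independent censoring
  lambda0 <- log(2) / 24
  hazard <- lambda0 *
    ifelse(sample_ids %in% risk_group, config$risk_hazard_ratio, 1)
  t_event <- stats::rexp(n, hazard)
  if (config$censoring_rate >= 1) {
    time <- stats::runif(n, 6, 72)
    event <- rep(0L, n)
  } else if (config$censoring_rate <= 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    cr <- config$censoring_rate
    t_cens <- stats::rexp(n, lambda0 * cr / (1 - cr))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  surv <- data.frame(sample_id = sample_ids,
                     time = pmax(time, 0.01), event = event,
                     stringsAsFactors = FALSE)

  # diagnosis/relapse differential table (consumed-engine emulation)
  n_diff_groups <- 15L
  diff_ids <- c(sprintf("d%02d", seq_len(n_diff_groups)),
                sprintf("rr%02d", seq_len(n_diff_groups)))
  up <- diff_planted[seq_len(ceiling(n_planted_diff / 2))]
  down <- setdiff(diff_planted, up)
  dshift <- matrix(1, nrow = n_total, ncol = 2L * n_diff_groups)
  relapse_cols <- n_diff_groups + seq_len(n_diff_groups)
  dshift[up, relapse_cols] <- 4
  dshift[down, relapse_cols] <- 0.25
  dcounts <- sim_counts(weights, dshift, config$depth, config$nb_size,
                        acr_ids, diff_ids)
  dcpm_lin <- compute_cpm(dcounts)
  dcpm <- log2(dcpm_lin + 1)
  grp_d <- seq_len(n_diff_groups)
  # fold change as a pseudocounted ratio of mean CPM (stable near zero)
  log2fc <- log2((rowMeans(dcpm_lin[, relapse_cols, drop = FALSE]) + 0.1) /
                   (rowMeans(dcpm_lin[, grp_d, drop = FALSE]) + 0.1))
  pvals <- vapply(seq_len(n_total), function(i) {
    x <- dcpm[i, relapse_cols]; y <- dcpm[i, grp_d]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  diff_table <- data.frame(acr_id = acr_ids, log2fc = log2fc,
                           fdr = stats::p.adjust(pvals, "BH"),
                           stringsAsFactors = FALSE)

  set.seed(config$seed + 97L)
  lines <- sprintf("line%02d", seq_len(config$n_cell_lines))
  drugs <- sprintf("drug%d", seq_len(config$n_drugs))
  z_drug <- matrix(stats::rnorm(config$n_drugs * config$n_cell_lines),
                   nrow = config$n_drugs, dimnames = list(drugs, lines))
  auc <- 50 + 10 * z_drug
  gene_ids <- sprintf("dg%04d", seq_len(config$n_drug_expr_genes))
  expr <- matrix(stats::rlnorm(config$n_drug_expr_genes *
                                 config$n_cell_lines, log(5), 0.8),
                 nrow = config$n_drug_expr_genes,
                 dimnames = list(gene_ids, lines))
  n_dg <- min(config$n_drug_genes, config$n_drug_expr_genes)
  dg_genes <- gene_ids[seq_len(n_dg)]
  # half the planted genes belong to the first drug (the "treatment" drug
  # whose response program the relapse ACRs rewire), rest spread out
  n_first <- ceiling(n_dg / 2)
  dg_drug <- c(rep(drugs[1L], n_first),
               rep(drugs[-1L], length.out = n_dg - n_first))
  r <- config$drug_correlation
  for (k in seq_len(n_dg)) {
    e <- r * z_drug[dg_drug[k], ] +
      sqrt(max(0, 1 - r^2)) * stats::rnorm(config$n_cell_lines)
    expr[dg_genes[k], ] <- pmax(0.01, 5 + 2 * e)
  }

  # ACR -> target-gene map: planted relapse-high ACRs preferentially hit
  # the first drug's response genes
  up_ids <- acr_ids[up]
  first_genes <- dg_genes[dg_drug == drugs[1L]]
  map_gene <- sample(gene_ids, n_total, replace = TRUE)
  if (length(up_ids) && length(first_genes)) {
    hit <- stats::runif(length(up_ids)) < 0.6
    map_gene[match(up_ids, acr_ids)[hit]] <-
      sample(first_genes, sum(hit), replace = TRUE)
  }
  acr_gene_map <- data.frame(acr_id = acr_ids, gene_id = map_gene,
                             stringsAsFactors = FALSE)

  list(
    survival = surv, cpm = cpm, risk_group = risk_group,
    diff_table = diff_table, acr_gene_map = acr_gene_map,
    expr = expr, auc = auc,
    truth = list(
      risk_acr_ids = acr_ids[risk_idx], risk_group = risk_group,
      relapse_high_acr_ids = acr_ids[up],
      relapse_low_acr_ids = acr_ids[down],
      drug_genes = data.frame(drug = dg_drug, gene = dg_genes,
                              correlation = r, stringsAsFactors = FALSE)
    ),
    config = config
  )
}
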