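---
title: "acrkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{acrkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrkit)
```

# Scope

`acrkit` implements the computational core of a chromatin-accessibility
analysis of a leukemia cohort profiled by ATAC-seq: construction of a
hierarchical accessible-chromatin-region (ACR) landscape from per-sample
peak calls, chromatin-state annotation, subtype-specific accessibility,
allele-specific open chromatin (ASOC), cis ACR-to-gene linking,
drug-response enrichment, and a relapse-free-survival (RFS) screen.
Upstream steps (read alignment, peak calling, chromatin-state model
training, motif scanning, negative-binomial differential testing) are
consumed as standard files, not re-implemented.

# The ACR hierarchy

Each ATAC-seq peak summit is extended 250 bp in both directions, giving a
501-bp ACR that inherits the peak's significance score
(&minus;log10 p). Within a sample, overlapping ACRs are resolved greedily:
sort by decreasing score, keep the best, discard everything it overlaps
(one shared base suffices), repeat. The same greedy rule drives every
merge level. Because raw significance scores are not comparable between
samples with different sequencing depth, each sample's scores are first
rescaled to sum to one million ("score per million") before sets are
pooled. Samples merge into patients (diagnosis + relapse; single-sample
patients pass through), patient sets are re-normalized on the normalized
scale, and one final pooled greedy pass gives the cohort-level landscape.
Re-normalizing the already-normalized scores is scale-invariant, so it
does not matter whether raw or normalized scores enter the patient-level
re-normalization; we re-normalize the normalized scores.

Tie-breaking on equal scores is by ascending (chromosome, start) so the
procedure is deterministic; summit windows that would cross position 0
are clamped and flagged rather than dropped. Both choices are ours — the
merging rule itself does not determine them.

Quantification consumes an externally counted ACR-by-sample fragment
matrix. CPM is plain per-column scaling (`counts * 1e6 / column total`);
an ACR is *recurrent* when log2(CPM) > 0 in at least two samples.

# Chromatin-state annotation

A consumed segmentation labels the genome with the eight collapsed
states TssA, Enh, BivR, Tx, Het, ZNF/Rpts, ReprPC and Quies; an 18-state
segmentation can be collapsed with a user-supplied two-column map
(`default_state_collapse()` provides a Roadmap-style grouping). Each ACR
receives the single state with the largest total base overlap, summed
across segments of the same state. The assignment rule for multi-state
ACRs is not dictated by the procedure we reproduce; maximal overlap is
the field's standard convention and we break exact ties by a fixed
active-first priority (TssA > Enh > BivR > Tx > ReprPC > Het >
ZNF/Rpts > Quies), assigning each ACR exactly once. ACRs with no
overlapping segment are Quies. Quies ACRs are further split into
gene-region versus distal by overlap with gene bodies extended by 5% of
the gene length on each side.

# Subtype-specific accessibility

An ACR is specific to a subtype when log2(CPM) > 1 in strictly more than
50% of that subtype's samples and in strictly less than 10% of all other
samples. Motif evidence is consumed as a precomputed hit table (scanning
of 101-bp summit-centered windows happens upstream); per (TF, subtype)
we report the fraction of the subtype's specific ACRs carrying the
motif.

Expression support uses a one-sided Wilcoxon rank-sum test
(enriched subtype vs the rest, alternative "greater"): exact null for
group sizes up to 10 without ties, tie-corrected normal approximation
otherwise. Fold change is a ratio of group means with a 0.01 FPKM
pseudocount in both numerator and denominator — the source procedure
does not define its fold change, and the pseudocount prevents division
by zero for silent genes. A TF passes at p < 0.05, fold change > 1.2
(strict) and an expression floor of log2(FPKM) > 1 in at least one
enriched-subtype sample. Target genes are those whose TSS lies within
1 kb of a subtype-specific ACR carrying the TF's motif (any overlap of
the 2-kb TSS window with the ACR interval — the inclusive reading).
Their evidence is aggregated as the geometric mean of per-target
p-values and the median per-target log2 fold change.

# Allele-specific open chromatin

At a heterozygous SNP with ATAC coverage `N = ref + alt`, the
alternate-allele fraction is compared to the balanced expectation of 50%
under a Gaussian null whose standard deviation (in percentage points)
depends on coverage:

$$\sigma(N) = 10.8\,(1 - e^{-N/83}).$$

The constants 10.8 and 83 are the trained values of the model and are
taken as given; we interpret sigma as percentage points of allele
fraction because 10.8 is only dimensionally sensible on that scale. The
test statistic is `z = |100 af - 50| / sigma(N)` with a two-sided normal
p-value, and `delta = |af - 0.5|` (so the 0.2 threshold means an allele
fraction outside [0.3, 0.7], mirroring the WGS heterozygosity band).
Note that sigma grows with coverage: a fixed percentage deviation
becomes *less* significant at higher coverage under this model.

Eligible SNPs are heterozygous in WGS (alt fraction 0.3–0.7,
inclusive), inside an ACR, with ATAC coverage at least 8 and at least 3
alternate reads (the alternate allele literally, not the minor allele).
Coverage counts ref + alt reads only; other bases are ignored. Per ACR,
SNP p-values are combined by Fisher's method (chi-square with 2k df on
&minus;2 Σ log p, p clamped at 1e-300) and deltas by arithmetic mean —
the combination method is unspecified in the source, and Fisher's method
degrades gracefully when one of several SNPs is balanced, unlike an
"any significant SNP" rule. An ACR is ASOC at combined p < 0.05 and
mean delta ≥ 0.2, otherwise biallelic (BiOC); ACRs without eligible
SNPs are not called at all. Candidate genes for an ASOC region are
flagged (e.g. COSMIC) genes within 200 kb of the ACR center expressed at
FPKM ≥ 1 in the same sample. The per-SNP test compares the ATAC
fraction to 0.5, not to the sample's WGS fraction; the WGS band already
restricts input sites to near-balanced genotypes.

# Cis ACR-to-gene links

Accessibility and expression matrices are pre-filtered to their top-75%
most variable rows. Candidate pairs lie on the same chromosome with ACR
center within 0.5 Mb of the gene TSS (anchors are our choice; the
procedure does not state them). Each pair is fit as a simple linear
association on z-standardized vectors, so the slope beta equals the
Pearson correlation and its p-value comes from the t-distribution on
n − 2 df — identical to a per-pair additive linear model with no
covariates, which is what the consumed external engine computes when run
without covariates. Batch correction of expression is assumed done
upstream. BH FDR is computed across all tested cis pairs (not per gene);
links are kept at |beta| > 0.2 and FDR < 0.05.

# Drug-response enrichment

Differential diagnosis-relapse tables are consumed (|log2FC| > 1,
FDR < 0.05 split into relapse-high/relapse-low). Drug-related gene sets
come from Pearson correlation of cell-line expression with drug AUC over
shared cell lines: pairs with |r| > 0.5 and p < 0.05. Enrichment of
differential-ACR target genes in each drug's set is a Fisher exact test
over the background of all genes entering the expression/AUC analysis —
the tested universe, not the whole genome — two-sided by default so
depletion is also detectable; both choices are configurable.

# Survival screen

For each recurrent ACR, relapse samples (one per patient) are split at
the median CPM — ties at the median go to the low group, a deterministic
convention of ours — and the two groups are compared by the standard
two-group log-rank test (computed via the survival package), with BH FDR
across all tested ACRs. Degenerate splits (constant rows) are skipped
and reported. RFS runs from diagnosis to first relapse.

# Synthetic cohorts

`sim_config()` fixes the desk-scale study conditions; all generators are
deterministic given the seed, with one seeded stream per data domain
(loci, counts, peaks, genes/expression, alleles, survival, drugs) so
enabling one component never shifts another's draws.

* **Counts.** 2000 study loci plus ~20 high-signal loci on a toy 2 × 20 Mb
  genome, negative-binomial counts (size 10 — the standard overdispersion
  model for ATAC fragment counts) at ~1e7 fragments per sample. The
  high-signal loci absorb 99.8% of the library so that study loci sit at
  CPM of order 1. This skew is deliberate: the absolute thresholds
  (log2 CPM > 0, > 1) are calibrated for a genome-wide landscape of
  hundreds of thousands of ACRs where the median CPM is near 1.6, and a
  few thousand uniformly covered loci would otherwise all sit far above
  threshold.
* **Subtype effects.** 24 samples in 4 subtypes (6 per subtype, matching
  the recovery analysis), planted loci at a narrow baseline just below
  the accessibility threshold (~0.85 CPM) shifted 4-fold in their
  subtype. With NB size 10, this placement gives per-sample
  above-threshold probabilities ≈ 0.9 inside and < 0.01 outside the
  subtype, hence ≥ 0.9 recovery without moving the calling thresholds.
* **Allelic reads.** 1–3 heterozygous SNPs per locus; WGS counts
  binomial(depth ≈ 40, 0.5); ATAC counts binomial(N, af) with N uniform
  in 30–200 and af = 0.85 (toward either allele) at planted ASOC loci.
* **Links.** 52 samples mirroring the linked-cohort size; planted genes
  are linear functions of their ACR's realized log2 CPM at correlation
  0.6 plus independent Gaussian noise, so the target correlation holds
  exactly in expectation regardless of the accessibility distribution.
* **Survival.** 42 relapse samples; exponential RFS with baseline median
  24 months and hazard multiplied by 4 for the planted risk half of the
  cohort; planted risk loci are 6-fold elevated in the risk group so the
  median-CPM split recovers the group. Censoring defaults to 10% —
  in a relapse cohort essentially every patient experiences the event,
  censoring only reflects loss to follow-up.
* **Drugs.** 11 cell lines, 8 drugs; planted response genes at
  correlation 0.8 with their drug's AUC, half of them belonging to the
  first drug, whose response program the planted relapse-high ACRs
  preferentially target in the ACR-to-gene map.

What the generators do **not** emulate: genomic sequence and mappability
structure, fragment-level duplication, GC and copy-number effects on
counts, linkage between neighboring SNPs, correlated gene programs, or
non-proportional hazards. Passing recovery tests on these cohorts shows
the decision rules and statistics behave as specified under their own
model assumptions, not that the thresholds are optimal for real data.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; SNP tables are accepted
  1-based and shifted on read. Chromosome names match as exact strings —
  no "chr" aliasing.
* Overlap means ≥ 1 shared base; abutting half-open intervals do not
  overlap.
* Empty ACR sets and zero score totals are errors for normalization;
  zero-total count columns are errors naming the sample.
* `log2(0)` is &minus;Inf and never passes a threshold; p-values are
  clamped at 1e-300 before Fisher combination; a zero sigma with an
  unbalanced allele fraction yields the smallest representable p and a
  flag.
* Constant vectors are skipped with warnings in link fitting and drug
  correlation; constant CPM rows are skipped with a reason in the
  survival screen.

# Problem sizes used in the checks

The package's own verification runs at deliberately small scale: 500
random instances for the merging oracle, 10,000 draws per coverage level
for the imbalance-test calibration, 2000 loci for ASOC recovery, 50
planted links among 1000 null cis pairs over 52 samples, and survival
screens of 1000 (null) and 200 (power) loci over 42 samples. These sizes
make each property measurable in seconds while leaving the Monte-Carlo
margins quoted in the tests comfortably narrow.

# Known limitations

* Differential accessibility and motif scanning are consumed, so the
  pipeline's end-to-end behavior depends on the quality of those inputs.
* The sigma model's constants are fixed; cohorts with very different
  coverage profiles would need re-training, which is out of scope.
* The survival screen assumes one column per patient; supplying both
  diagnosis and relapse samples of a patient would double-count.
* Fisher's method treats SNPs within an ACR as independent, which
  understates combined p-values when SNPs share fragments.
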