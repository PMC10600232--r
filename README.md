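# acrkit

Analysis toolkit for accessible chromatin region (ACR) landscapes in
leukemia ATAC-seq cohorts — built for studies that profile tumor samples
at diagnosis and relapse and ask how chromatin accessibility relates to
molecular subtype, allelic regulation, gene expression, drug response
and prognosis. Raw patient data in such studies are typically
controlled-access, so the package ships seeded synthetic-cohort
generators with planted ground truth that exercise every stage.

## What it computes

* **ACR hierarchy** — each peak summit is extended ±250 bp into a 501-bp
  ACR carrying the peak's −log10 p score. Overlaps are resolved greedily
  by significance (keep the best, drop what it overlaps). Per-sample
  scores are rescaled to sum to 10⁶ ("score per million") so samples of
  different depth are comparable; sample sets merge into patient sets
  and then into the cohort landscape by the same greedy rule on
  normalized scores. Quantification is CPM
  (counts × 10⁶ / column total); ACRs with log₂(CPM) > 0 in ≥ 2 samples
  are *recurrent*.
* **Chromatin-state annotation** — each ACR gets the state (of TssA,
  Enh, BivR, Tx, Het, ZNF/Rpts, ReprPC, Quies) with maximal base
  overlap; Quies ACRs are split into gene-region vs distal using gene
  bodies extended by 5% of their length.
* **Subtype-specific ACRs** — log₂(CPM) > 1 in > 50% of the subtype and
  < 10% of all other samples; TF motif fractions plus one-sided
  Wilcoxon expression tests with geometric-mean p and median log₂ FC
  aggregation over target genes (TSS ± 1 kb).
* **Allele-specific open chromatin (ASOC)** — at heterozygous SNPs
  (WGS alt fraction 0.3–0.7, ATAC coverage ≥ 8, alt reads ≥ 3, inside an
  ACR), the ATAC allele fraction is tested against 50% under a Gaussian
  null with coverage-dependent spread σ(N) = 10.8·(1 − e^(−N/83))
  percentage points; SNPs combine to ACR calls by Fisher's method and
  mean delta, with ASOC at p < 0.05 and |delta| ≥ 0.2.
* **Cis ACR-to-gene links** — standardized per-pair regression (beta =
  Pearson r, t-test p) over pairs within 0.5 Mb, BH FDR; links kept at
  |beta| > 0.2, FDR < 0.05.
* **Drug-response enrichment** — drug gene sets from |r| > 0.5, p < 0.05
  expression–AUC correlations across cell lines; Fisher exact enrichment
  of differential-ACR (|log₂FC| > 1, FDR < 0.05) target genes.
* **Survival screen** — per recurrent ACR, relapse samples split at the
  median CPM and compared by log-rank test; BH FDR < 0.05 defines
  RFS-related ACRs.

See `vignettes/acrkit-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

```r
library(acrkit)

cfg <- sim_config(seed = 42)            # desk-scale cohort, known truth
sim <- simulate_cohort(cfg)

# peaks -> sample -> patient -> cohort ACRs
patients <- setNames(sim$labels$patient_id, sim$labels$sample_id)
cohort <- build_cohort_acrs(sim$peaks, patients)
nrow(cohort)
#> [1] 2020

# quantify, filter, call subtype-specific ACRs
cpm <- compute_cpm(sim$counts)
recurrent <- filter_recurrent(cpm)
length(recurrent)
#> [1] 1465
spec <- call_subtype_specific(cpm[recurrent, ], sim$subtypes)
lengths(spec)
#> S1 S2 S3 S4
#> 26 25 26 25

# 99 of the 100 planted subtype effects are among the calls
sum(unlist(lapply(names(spec), function(s)
  sim$truth$subtype_specific[[s]] %in% spec[[s]])))
#> [1] 99

# allele-specific open chromatin on the same seeded truth
ar <- simulate_allelic_reads(cfg)
calls <- call_acr_asoc(test_snp_imbalance(filter_het_snps(ar$snps, ar$acrs)))
table(calls$label)
#> ASOC BiOC
#>   49 1943
head(calls[calls$label == "ASOC",
           c("acr_id", "n_snps", "combined_p", "combined_delta")], 3)
#>      acr_id n_snps   combined_p combined_delta
#> 41  acr0041      1 1.971460e-05      0.3930818
#> 78  acr0078      1 5.837084e-11      0.3200000
#> 119 acr0119      3 3.028356e-20      0.3491540
```

Every cohort ACR corresponds to one simulated locus; about 72% pass the
recurrence filter at this depth; the subtype caller recovers 99 of 100
planted effects and assigns none to a wrong subtype; 49 of the 50
planted imbalanced loci are called ASOC (one planted locus drew no
eligible SNP) with combined allele-fraction deviations well above the
0.2 threshold.

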