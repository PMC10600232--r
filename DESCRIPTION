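Package: acrkit
Title: Accessible Chromatin Region Analysis for Leukemia ATAC-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hierarchical accessible chromatin region (ACR) landscapes
    from ATAC-seq peak calls by summit extension, score-per-million
    normalization and significance-ranked overlap resolution; annotates ACRs
    with collapsed chromatin states; calls subtype-specific ACRs and tests
    transcription-factor and target-gene expression with geometric-mean
    aggregation; detects allele-specific open chromatin at heterozygous SNPs
    with a coverage-dependent Gaussian model; links ACRs to candidate target
    genes in cis; tests enrichment of differential-ACR targets in
    drug-response gene sets; and screens ACRs for association with
    relapse-free survival. Includes seeded synthetic-cohort generators with
    planted ground truth so every stage is testable without controlled-access
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
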