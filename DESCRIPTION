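Package: aiscape
Title: Allelic Imbalance Landscape Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the allelic imbalance (AI) landscape of a
    tumor cohort from SNP-level B-allele frequency (BAF) and log R ratio
    (LRR) signals. Calls AI segments per sample by penalized least-squares
    changepoint detection on mirrored BAF, classifies them into gains and
    losses (including copy-neutral LOH) by mean LRR, builds cohort-level
    recurrence count tracks, detects recurrence peaks ranked by topographic
    prominence, assigns candidate target genes, calls isochromosome-like
    arm events, scans within-chromosome gain/loss co-occurrence, relates
    somatic point-mutation density to chromosomal copy number, and provides
    burden-controlled logistic association tests, contingency and
    hypergeometric enrichment statistics, purity and clonality estimation,
    and a synthetic tumor-cohort generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
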