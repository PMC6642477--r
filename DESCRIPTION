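Package: mlpacnv
Title: Copy Number Variant Calling and Cohort Summaries for MLPA Pharmacogene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex ligation-dependent probe
    amplification (MLPA) copy-number profiling of pharmacogenes (CYP-450 and
    GST families). Takes per-sample per-probe peak heights through
    intra-sample (reference-probe) and inter-sample (reference-sample)
    normalization to dosage quotients, classifies each probe into copy-number
    classes, aggregates exon-level calls to gene-level CNV diplotypes, and
    summarizes cohorts as genotype and allele frequency tables, mutational
    status categories, carrier groups and per-gene CNV censuses. Includes a
    synthetic peak-signal and cohort simulator for validation, control
    fragment quality checks, predicted metabolizer phenotypes, and a sample
    size calculator for proportion estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
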