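Package: lfqpipe
Title: Label-Free Proteomics Differential Expression with Split-Cohort
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for label-free quantitative
    proteomics of paired-design immune-cell cohorts: contaminant removal,
    log2 transformation, stratum-wise valid-value filtering, seeded
    downshifted-normal imputation of left-censored missing abundances,
    stratified differential expression (paired t-tests for the
    stimulation contrast, Welch tests for patient-control contrasts)
    with Benjamini-Hochberg correction, principal component analysis
    with a uniform-contribution influential-loading cutoff, a
    split-cohort resampling validation of group separation on the first
    principal component, and chi-squared enrichment of differential
    proteins in a susceptibility gene set. Includes a synthetic-cohort
    generator with planted effects and intensity-dependent missingness
    so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
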