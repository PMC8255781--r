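Package: pharmaeeg
Title: Pharmaco-EEG Band Power Pipeline with Rank-Based Longitudinal Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent pharmaco-EEG studies: a 70-channel
    FIR filter-bank with Hilbert envelope power extraction, artifact-robust
    4-s epoch median power, aggregation into the seven classical frequency
    bands (delta through gamma2), baseline total-power and pretreatment-mean
    normalization, and nonparametric rank-based tests for longitudinal
    factorial designs (F1-LD-F1 and F2-LD-F1 layouts; Wald-type and
    ANOVA-type statistics with Bonferroni-corrected post-hoc time-bin
    comparisons). Includes a synthetic EEG/EMG generator with known band
    structure, genotype effects, drug-effect time courses and ground-truth
    artifact masks, plus minimal EDF and TSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
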