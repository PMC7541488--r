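Package: scregact
Title: Tissue-Specific TF Regulons and Single-Cell Regulatory Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers tissue-specific transcription factor (TF) regulons from
    multi-tissue bulk RNA-Seq data using a greedy partial-correlation
    framework, and estimates per-cell TF regulatory activity in single-cell
    RNA-Seq data as the t-statistic of regressing a cell's z-scored
    expression profile on the signed regulon. Includes an analytic power
    model for detecting tissue-specific TFs in bulk data based on the
    non-central t distribution, differential-activity statistics with
    Monte-Carlo regulon nulls, sensitivity/precision benchmark metrics, a
    threshold-free Wilcoxon-AUC regulon score, and synthetic-data
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
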