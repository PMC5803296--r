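Package: duosig
Title: Dual-Cohort Islet Transcriptomic Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for deriving a cross-cohort
    concordant differential-expression signature from two independent
    bulk expression cohorts (e.g. enzymatically isolated organ-donor
    islets and laser-capture-microdissected islets from pancreatectomised
    patients). Provides expression/sample quality-control filters,
    parametric empirical-Bayes location-scale batch adjustment,
    empirical-Bayes moderated t-statistics with Benjamini-Hochberg
    control, hypergeometric overlap testing, weighted co-expression
    modules with eigengenes and module-trait correlation, and upstream
    transcription-factor inference merging a signed literature channel
    with a sequence-motif enrichment channel. Ships a synthetic
    two-cohort data generator with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    cluster,
    jsonlite,
    yaml
Config/testthat/edition: 3
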