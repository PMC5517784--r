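Package: opcflux
Title: Reference-Gene Stability, Differential Expression and Cumulative
    Flux Index Scoring for CSF-Treated Oligodendrocyte Progenitor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for one-color microarray expression
    data from oligodendrocyte progenitor cell (OPC) cultures exposed to
    patient cerebrospinal fluid (CSF) across multiple sclerosis and
    neuromyelitis optica clinical subtypes. Implements 75th-percentile
    array normalization, pooled-quantile low-expression filtering and
    probe-to-gene merging; from-scratch geNorm (average pairwise
    log-ratio variation M) and NormFinder (model-based intra-/inter-group
    variance decomposition) reference-gene stability ranking; reference
    normalization, fold-change and ANOVA/Tukey/FDR differential-expression
    calling; and a multiplicative Cumulative Flux Index (CFI) that scores
    glucose-metabolism pathway impairment (glycolysis, TCA cycle, electron
    transport chain) per condition. A seeded synthetic-data module emulates
    the study design (6 conditions x 4 replicate arrays) so every stage is
    testable without the unavailable raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
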