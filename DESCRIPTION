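Package: sgascore
Title: Interaction Scoring for Inducible Synthetic Genetic Array Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores colony-array genetic screens in which a query construct
    is switched on (for example by doxycycline induction) and fitness is
    read out as colony area on replica-pinned agar plates.  Provides
    missing-aware spatial and row/column normalization of plate grids,
    jackknife and low-area replicate filters, median-ratio W statistics and
    the multiplicative interaction score S = Wij - Wi x Wj, an
    empirical-Bayes moderated fold-change-threshold test with
    Benjamini-Hochberg false-discovery-rate control, interaction
    classification against a control query, a compound-interaction variant
    for petite and drug-treatment screens, correlation of fitness-defect
    profiles against a reference chemogenomic matrix, and a synthetic
    screen generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
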