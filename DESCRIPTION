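Package: panpcd
Title: Pan-Programmed-Cell-Death Panel Derivation, Single-Cell Scoring, and
    Signature-Reversal Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pan-programmed-cell-death (pan-PCD) activity
    after tissue injury. Curates multi-pathway cell-death gene catalogs from
    GMT collections, derives injury-specific core gene panels from bulk
    differential expression across injury models (empirical-Bayes moderated
    t-statistics, strict fold-change/p thresholds, cross-model Wilcoxon
    rank-sum filtering), scores single cells for panel activity with a
    rank-based recovery-curve AUC and an expression-matched module score,
    stratifies cells at an automatically detected bimodal threshold, compares
    groups with ordinary-least-squares score slopes and bootstrap slope
    ratios, and screens perturbation-profile libraries for
    signature-reversing compounds with Kolmogorov-Smirnov connectivity
    scores, permutation p-values, and a multi-dataset consensus rule.
    Includes seeded synthetic-data generators with planted ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
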