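Package: pmtstats
Title: Statistics for Detecting a Pericyte-to-Myofibroblast Transition in
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lineage-resolved trajectory statistics and subject-level
    proportion models for detecting a genotype-associated
    pericyte-to-myofibroblast transition in single-nucleus RNA-seq data.
    Implements binned-control gene-program scoring with a co-expression
    (minimum) score, marker-threshold gating of intermediate cells, weighted
    penalized B-spline trajectory fits with a delta-AUC permutation test
    between lineages, a subject-level lineage-bias permutation test, binomial
    logit regression of cell-state proportions with natural-spline age terms
    and Wald odds ratios, greedy propensity-score matching with covariate
    balance reporting, randomized-quantile residual diagnostics, and
    marker-threshold cell-state classification statistics on labeled tissue
    images (vessel distance, proximity fractions, trend tests). A synthetic
    cohort, count, and tissue-image generator with known ground truth
    supports calibration and power analysis of every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    splines,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
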