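Package: scDR
Title: Drug-Response Signature Scoring for Bulk and Single-Cell Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives per-drug response gene signatures from pharmacogenomic
    training data (AUC-based resistant/sensitive cell-line labelling followed
    by fold-change ranking) and scores any expression profile -- bulk sample
    or single cell -- with a fold-change-weighted z-score statistic, the
    drug-response score (DRS). Includes readers for dense and MatrixMarket
    sparse expression matrices, single-cell quality-control filtering and
    library-size normalization, cell-to-cell-line score aggregation (mDRS),
    a validation framework (one-sided Wilcoxon separation tests, threefold
    cross-validation with min-max rescaling and permutations, weighted
    probabilistic concordance index for method comparison), and a seeded
    synthetic-cohort generator for bulk and overdispersed single-cell counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
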