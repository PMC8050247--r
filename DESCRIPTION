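Package: metsum
Title: Balanced Sparse Logistic Classification and Ingredient
    Decomposition for Binary Metabolomic Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for repository-scale analysis of binary (presence/absence)
    tandem mass spectrometry feature tables. Provides a class-balanced,
    sparsity-regularized logistic classifier of biological and clinical
    phenotypes with interpretable biomarker ranking and a
    remove-and-retrain loop for auditing batch-effect artifacts such as
    internal standards; and a sparse decomposer that expresses a complex
    sample's binary metabolome as a small set of raw-ingredient reference
    profiles by minimizing a balanced cross-entropy plus L1 objective
    along a regularization path until a target support size is reached.
    Includes readers and writers for dense and MatrixMarket feature
    tables, a synthetic-data generator for union-composed mixtures and
    protocol-confounded cohorts, and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
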