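Package: genofold
Title: Genetic Folding of Support Vector Machine Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evolves custom support vector machine kernel functions by the
    genetic folding strategy. Candidate kernels are encoded as linear
    chromosomes of operator/terminal pairings, decoded into expression
    trees over vector and scalar arithmetic, scored by cross-validated
    accuracy of a soft-margin SVM trained on the (eigenvalue-repaired)
    precomputed Gram matrix, and improved by roulette-wheel selection with
    symbol mutation and elitism. Includes the linear, polynomial and
    radial basis baseline kernels, stratified cross-validation and
    classification metrics (accuracy, ROC AUC, mean squared error), a
    kernel comparison harness, a clinical-survey style synthetic data
    generator with a configurable planted (optionally nonlinear) signal,
    and a small command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
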