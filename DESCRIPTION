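Package: fsmlknn
Title: Multi-Label k-Nearest Neighbour Models with Feature Selection for
    Drug Side-Effect Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts drug side-effect profiles as a multi-label learning
    problem over binary drug descriptors (chemical substructures, targets,
    enzymes, transporters, pathways, indications).  Implements the Bayesian
    multi-label k-nearest neighbour learner (MLKNN), a two-stage feature
    selection wrapper combining a mutual-information filter with a genetic
    algorithm whose fitness is internal cross-validated AUPR (FS-MLKNN),
    and a weighted-scoring ensemble that fuses per-feature-type models with
    genetic-algorithm-tuned simplex weights.  Ships the full multi-label
    evaluation suite (micro AUPR/AUC, Hamming loss, ranking loss, one-error,
    coverage, average precision, per-label AUPR, top-N recall), a seeded
    synthetic-data generator with planted informative dimensions, and
    cross-validation / independent-split experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
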