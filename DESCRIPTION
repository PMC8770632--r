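Package: kerndep
Title: Diffusion-Kernel Network Variable Selection for Gene-Dependency Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting cancer cell-line gene dependency from
    transcriptome data using protein-protein interaction networks. Builds a
    score-filtered, shell-restricted interaction network around a focal gene
    from STRING-style edge lists, ranks candidate predictor genes by diffusion
    kernel (heat kernel) centrality, filters them by minimum expression, and
    fits penalized-regression ensembles (lasso, elastic net, random forest)
    over repeated 80/20 holdout splits, evaluated by the Pearson correlation
    of averaged test-set predictions. Includes cohort classification rules
    (wild-type/mutant, dependent/independent, amplification, binary
    RAS-activating-event markers), predictor-frequency and exclusion analyses,
    and a synthetic DepMap-shaped data generator with planted signal so the
    complete workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
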