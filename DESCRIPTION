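Package: thyropanel
Title: Protein-Panel Classification of Thyroid Nodules
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating protein-panel diagnostic
    classifiers for thyroid nodules from label-free proteomic abundance
    matrices. Provides a synthetic DIA-style cohort simulator with
    missing-not-at-random censoring, detection-limit imputation with
    discovery-anchored z-score normalization, genetic-algorithm selection
    of fixed-size protein panels under cross-validated fitness, a
    manifold-regularized multilayer-perceptron classifier trained with a
    cross-layer two-way divergence loss, diagnostic-performance reporting
    with Wilson score intervals and prevalence re-projection, and pairwise
    differential-expression counting between histological groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
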