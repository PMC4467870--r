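Package: tomauth
Title: Chemometric Characterization and Authentication of Tomato Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing and authenticating tomato samples from
    their chemical composition. Implements a tree-structured Automatic
    Interaction Detection procedure driven by three-way factorial General
    Linear Models (GLM-AID) with Bonferroni homogeneous subsets, a
    single-hidden-layer sigmoid multilayer perceptron trained by online
    backpropagation with momentum, weight-sum input importance with variable
    reduction, and Average-Percentage-of-Success evaluation. A seeded
    synthetic cohort generator emulates an unbalanced 5x3x4 factorial survey
    of 25 chemical parameters (sugars, organic and hydroxycinnamic acids,
    minerals, lycopene, phenolics) so the full pipeline is reproducible
    without access to the original laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
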