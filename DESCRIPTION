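Package: waterkrig
Title: Local-Structure-Aware Kriging of Atomistic Properties in Water Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-process (simple kriging) regression for scalar atomistic
    properties of a central water molecule inside a small water cluster.
    Provides atom-centered spherical-polar coordinate frames, twelve
    permutation-aware feature-definition schemes (atomic-index, sorted-distance
    and tetrahedral-node "structured" orderings, each in an oxygen- or
    hydrogen-centered frame), concentrated log-likelihood hyperparameter
    optimization by particle swarm or differential evolution, fivefold
    cross-validation with MAE and q-squared reporting, S-curve error
    distributions, and a synthetic decamer generator with permutation-invariant
    surrogate property labels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
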