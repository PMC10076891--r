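Package: qsardnn
Title: Deep Neural Network QSAR Regression with q-Squared Cost, Data
    Washing and Sphere-Exclusion Splitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling
    with a feed-forward tanh neural network trained by stochastic gradient
    descent against a cost that maximises the correlation coefficient
    q-squared under L2 weight decay, with inverted dropout and early
    stopping.  Includes the surrounding data-preparation pipeline:
    normalization, Pauta-criterion (3-sigma) outlier washing with a local
    similar-compound significance rule, greedy correlation-based descriptor
    pruning, optional PCA reduction, and rational training/test division by
    sphere exclusion.  A wrapper searches descriptor subsets of fixed size,
    re-splitting and retraining per subset.  Synthetic descriptor tables
    with known generative structure support fully reproducible testing.
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
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
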