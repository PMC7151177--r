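Package: apclass
Title: One-Shot Associative Pattern Classification with Mean-Translation
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the associative pattern classifier (APC), a
    one-shot associative-memory classifier that combines the Hebbian
    outer-product learning rule of the linear associator with the
    maximum-activation recovery rule of the Lernmatrix, applied to
    mean-translated real-valued feature vectors with one-hot class
    labels.  Includes explicit neutral-zone and tie semantics with a
    reject option, a reader for the Wisconsin Breast Cancer (Original)
    file dialect and generic labeled CSV with declared missing-value
    policies, a seeded two-class Gaussian synthetic data generator,
    a native nearest-centroid baseline, stratified repeated-holdout and
    k-fold evaluation protocols, learning curves, optional adapters to
    established baseline classifiers, and a command-line interface.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    e1071,
    nnet,
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
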