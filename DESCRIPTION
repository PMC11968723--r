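Package: eposelect
Title: Eagle Prey Optimization for Wrapper Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional gene-expression
    classification using the Eagle Prey Optimization (EPO) metaheuristic.
    Provides the continuous EPO optimizer (Levy-flight search, spiral
    coefficients, adaptive exploration schedule), sigmoid binarization to
    gene masks, a composite fitness balancing classification accuracy,
    subset sparsity and redundancy, adapters for five standard classifiers,
    0.632+ bootstrap error estimation with overfitting diagnostics,
    paired significance tests, a synthetic microarray-like data generator
    with planted informative and redundant genes, and ARFF/CSV input and
    output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
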