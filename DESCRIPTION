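Package: mlrecommend
Title: Collaborative-Filtering Recommendation of Machine Learning
    Algorithm Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An engine for recommending machine learning algorithm
    configurations to run on tabular classification datasets, treating a
    knowledge base of past experiment results as a sparse ratings matrix in
    which datasets play the role of users and algorithm configurations the
    role of items. Implements a biased matrix-factorization recommender
    trained online by stochastic gradient descent, neighborhood, slope-one,
    co-clustering, metafeature (metalearning) and control strategies behind
    one interface, together with a simulation framework that measures how
    quickly each strategy learns to propose near-optimal configurations in
    terms of relative balanced-accuracy regret and success-rate curves.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
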