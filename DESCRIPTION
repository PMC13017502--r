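Package: zipflearn
Title: In-Context Versus In-Weights Learning Under Zipfian Training Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how the diversity and
    redundancy of training data drive in-context versus in-weights learning in
    minimal transformer networks and matched baselines. Provides Zipfian,
    composite and curriculum training distributions with deterministic
    human-style block allocations; an item-label sequence task with in-context,
    in-weights and arbitrage test probes and a transitive-inference variant;
    hand-written attention-only transformer, MLP and LSTM learners trained with
    Adam; evaluation metrics including the double-learning index and
    induction-head attention-template diagnostics; and a synthetic
    behavioural-cohort simulator with logistic/linear group contrasts and
    BIC-approximated Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    withr,
    sandwich,
    grid,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
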