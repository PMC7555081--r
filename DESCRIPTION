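Package: regionage
Title: Regional Brain-Age Modelling and Parity Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for regional brain-age analysis on
    morphometric feature tables: hierarchical clustering of regional volumes
    on Spearman rank correlations, cross-validated gradient-boosted (or
    linear) brain-age prediction per feature set, age-bias-corrected
    brain-age deltas, and association testing against an exposure count
    (number of childbirths) with correlated-estimates Z tests,
    Benjamini-Hochberg false-discovery-rate control, leave-one-out
    log-likelihood comparisons under Wilks' theorem, and weighted polynomial
    group fits. Includes a calibrated synthetic-cohort generator emulating a
    large population imaging study of middle- and older-aged women, so every
    stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
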