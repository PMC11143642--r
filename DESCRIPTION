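Package: culturopt
Title: Surrogate Modelling and Multi-Objective Optimization of In Vitro
    Culture Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model in vitro plant growth responses to plant growth
    regulator doses and to optimize the dose combination. Regenerates a
    factorial dose-response dataset from published per-treatment summary
    statistics (three pomegranate cultivars, gibberellic acid x zeatin),
    fits five tuned regression surrogates (support vector regression,
    random forest, gradient boosting, elastic net, and a stacking
    ensemble) with a tree-structured Parzen estimator tuner under k-fold
    cross-validation, ranks them with the Global Performance Indicator,
    and couples the winning surrogate to the NSGA-II genetic algorithm to
    recover Pareto-optimal dose pairs and a single compromise
    recommendation per cultivar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    ranger,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
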