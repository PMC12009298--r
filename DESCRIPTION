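Package: introchoice
Title: Inferring Multi-Attribute Choice Processes and Scoring Introspective
    Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how people make two-alternative,
    multi-attribute choices and how accurately they can report on their own
    choice process. Implements a six-model family of choice strategies built
    from three composable heuristics (single-attribute / take-the-best,
    binary weights / equal weights, binary attribute values / weighted pros)
    over a weighted-additive softmax core; per-participant Bayesian model
    comparison via exact quadrature for the discrete models and Laplace
    importance sampling for the continuous ones; model-averaged attribute
    weights; introspective-accuracy metrics with bootstrap chance levels; a
    synthetic-data generator for tasks, deciders and self-reports; and a
    seeded model-recovery study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
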