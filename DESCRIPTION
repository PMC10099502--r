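Package: fpchoice
Title: Outlet Choice and Willingness to Travel for Family Planning Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models where women obtain contraception when several service
    delivery points compete within walking distance.  Provides a synthetic
    study generator that emulates a linked household-outlet census (outlets
    of three types in an outer ring, surveyed households in an inner ring),
    radius-limited choice-set construction with Euclidean distances,
    supply-environment summaries, a six-category multinomial logit of
    method-use and outlet-linkage status yielding inverse-probability
    weights, weighted conditional and mixed (random-coefficient) logit
    estimation by maximum simulated likelihood with Halton draws, and
    willingness-to-travel statistics with delta-method or simulation
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
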