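Package: lccsim
Title: Stochastic Spatially Explicit Modelling of Land Cover Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for fitting and simulating stochastic, spatially explicit
    models of land cover change among three classes (forest, regeneration,
    deforested). Per-pixel transition probabilities follow a logistic model of
    landscape drivers (distance to roads, rivers and settlements, protection
    status, neighbourhood contagion and land-use history metrics), fitted by
    Metropolis-Hastings sampling with forward stepwise covariate selection
    scored by held-out likelihood. A contagion-updating forward simulator
    propagates posterior parameter uncertainty through repeated stochastic
    iterations; predictions are scored against observed maps with a
    perfect-match metric restricted to observed change. Includes calibration
    window experiment designs, temporal parameter-trend analysis, and a
    synthetic-landscape generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
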