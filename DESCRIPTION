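Package: habscape
Title: Scenario-Driven Land-Use Simulation and Habitat-Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples Markov-chain land-demand projection, neural-network
    land-suitability mapping and a cellular-automaton allocation with
    self-adaptive inertia and competition, with habitat-quality and
    degradation scoring driven by distance-decayed threat kernels.
    Ships four planning-scenario configurations (business-as-usual,
    fast cultivated-land expansion, ecological security, sustainable
    development), a synthetic-landscape generator for fully reproducible
    end-to-end runs, kappa/overall-accuracy map validation, and grade-based
    scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nnet,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
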