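Package: ligninGMA
Title: Ensemble Modeling of Monolignol Biosynthesis with Generalized
    Mass Action Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and screens ensembles of normalized generalized
    mass action (GMA) models of the monolignol biosynthesis pathway in
    switchgrass. Provides the pathway topology under three candidate
    configurations of a putative CCR1/CAD metabolic channel, a flux
    balance analysis stage that anchors rate constants, constrained
    Monte Carlo and Latin hypercube sampling of kinetic orders with
    product-inhibition ratio bounds, steady-state knockdown simulation,
    screening against transgenic lignin fold-change data, principal
    component analysis of the accepted ensemble, and multi-enzyme
    perturbation scenarios for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    deSolve,
    jsonlite,
    lhs,
    quadprog,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
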