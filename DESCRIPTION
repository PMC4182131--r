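Package: lactokin
Title: State-Consistent Monte-Carlo Kinetic Modeling of Lactococcus lactis
    Central Metabolism
Version: 0.1.0
Authors@R:
    person("lactokin", "developers", email = "lactokin@example.org",
           role = c("aut", "cre"))
Description: Ensemble kinetic modeling of the fermentative central carbon
    metabolism of Lactococcus lactis. Kinetic parameters (Michaelis and
    regulation constants) are Monte-Carlo sampled so that every model
    instance exactly reproduces an observed metabolic state, defined by a
    mass-balanced steady-state flux distribution and a thermodynamically
    feasible set of metabolite concentrations. The package computes
    probabilistic distributions of scaled flux and concentration control
    coefficients, filters instances by linear stability of the reduced
    Jacobian, simulates starvation/recovery protocols with a stiff
    Rosenbrock integrator, detects bistability and hysteresis by
    quasi-static glucose sweeps, and screens the contribution of individual
    allosteric regulatory interactions (notably the feedforward activation
    of pyruvate kinase by fructose-1,6-bisphosphate) to metabolic stability
    and recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
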