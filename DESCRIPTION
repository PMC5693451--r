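Package: cccsim
Title: Simulation and Analysis of Carrier Cycling Cascades in Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of the carrier cycling
    cascade (CCC), a minimal metabolic motif in which a moiety-conserved
    coenzyme pool (ATP/ADP, NADH/NAD+) couples an active-carrier-consuming
    step to an active-carrier-producing step. Provides the full mass-action
    model with complex formation, its adiabatic five-ODE reduction and the
    conservation-law two-ODE reduction; phase-plane tools (nullclines,
    steady states); the closed-form jamming threshold of the influx rate and
    numerical relaxation-time scans exhibiting critical slowing down;
    frequency-response analysis of sinusoidally driven influx with the
    analytic low-pass cut-off; exact Gillespie simulation with Fano-factor
    statistics and chemical-master-equation oracles for the noise
    suppression by carrier feedback; estimation of enzyme turnover rates
    from measured pathway concentrations and fluxes; and coupled cascades
    sharing one carrier pool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
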