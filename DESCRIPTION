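Package: abcsld
Title: Approximate Bayesian Computation with Simulated Likelihood Density
    for Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Likelihood-free Bayesian inference of stochastic rate constants
    in discrete-state mass-action reaction networks. Provides an exact
    Gillespie direct-method simulator with restart-from-state support,
    sequential Monte Carlo particle samplers whose acceptance error is built
    from the simulated likelihood (transitional) density -- either per
    observation interval or over whole trajectories -- and a generic ABC SMC
    baseline, together with diagnostics (mean count number, averaged error,
    posterior histograms) and two built-in benchmark systems: a reversible
    dimerization model and a prokaryotic auto-regulatory gene network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
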