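Package: dosefindsim
Title: Simulation of Phase I Dose-Finding Designs: Accelerated Titration
    and Escalation with Overdose Control
Version: 0.1.0
Authors@R:
    person("dosefindsim", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and compares the operating characteristics of
    rule-based accelerated titration (3+3 / modified-Fibonacci up-and-down)
    designs and Bayesian escalation with overdose control (EWOC and its
    proportional-odds variant EWOC-PO) for phase I cancer dose-finding
    trials on a continuous standardized dose scale.  Provides trinary
    (grade 0-1 / grade 2 / DLT) dose-toxicity generating models, an exact
    state-machine implementation of the two-phase accelerated titration
    algorithm, a Metropolis-Hastings sampler for the EWOC posterior with
    the feasibility-bound dose-selection rule, a reproducible factorial
    trial engine, and safety/efficiency summaries (bias, root MSE, DLT-rate
    distributions, optimal-dose proportions, trial-size percentiles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
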