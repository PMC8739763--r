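Package: txseq
Title: Decision-Analytic Markov Model for Kidney Transplant Sequencing
Version: 0.1.0
Authors@R: person("txseq", "maintainers", email = "txseq@example.org", role = c("aut", "cre"))
Description: Yearly-cycle Markov cohort model comparing lifetime outcomes of
    live-donor-first versus deceased-donor-first kidney transplant sequencing
    for recipients starting at ages 3-25. Provides age-stratified rate tables,
    rate-to-probability conversions under a constant-hazard assumption, a
    deterministic cohort solver and an individual-level microsimulation oracle,
    Monte Carlo probabilistic sensitivity analysis with log-normal parameter
    perturbation and percentile confidence intervals, scenario grids for
    availability, candidacy and preemption assumptions, a synthetic rate-table
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
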