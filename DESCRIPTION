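Package: yegrowth
Title: Macro-Kinetic Modelling of Escherichia coli Growth in Yeast-Extract Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and parameter estimation for an extended macro-kinetic
    growth model of Escherichia coli in glucose media supplemented with yeast
    extract. Yeast extract is lumped into up to three kinetic fractions (fast,
    slow, unconsumed), whose uptake inhibits the oxidative glucose pathway and
    thereby modulates overflow metabolism and acetate cycling. The package
    integrates the model over batch and fed-batch horizons (stepwise,
    exponential and bolus feeding with evaporation), fits parameters to
    weighted time-series measurements of biomass, glucose, acetate and
    dissolved oxygen by robust-scaled least squares under a bounded
    Nelder-Mead search, selects identifiable parameter subsets from dynamic
    sensitivities, and quantifies parameter uncertainty by Monte-Carlo
    replication with Latin hypercube restarts, IQR outlier filtering and
    Student-t confidence intervals. A synthetic-data generator emulating
    at-line and online sampling makes the whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
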