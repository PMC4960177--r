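Package: chokinetics
Title: Kinetic Modelling of Growth, Glucose Consumption and Antibody
    Production in CHO Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-modified Monod growth kinetics and Luedeking-Piret
    monoclonal antibody production kinetics for naive and recombinant Chinese
    hamster ovary (CHO) cell batch and fed-batch cultures. Provides parameter
    estimation from culture time series (log-linear specific growth rate,
    Lineweaver-Burk linearization with a substrate threshold, through-origin
    yield regression, direct and integral Luedeking-Piret fits, temperature
    recalibration), polynomial-smoothing rate machinery with specific rates
    normalized by the integral of viable cells, forward simulation of batch and
    fed-batch bioreactor cultures with feed-event dilution balances and
    temperature-shift parameter switching, a shipped registry of fitted
    parameter sets, and a design-matched synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
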