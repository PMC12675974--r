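Package: laiskfit
Title: Laisk-Method Estimation of the Photorespiratory CO2 Compensation
    Point and Day Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the photorespiratory CO2 compensation
    point (gamma-star) and the rate of CO2 release in the light (D_L) from
    leaf gas-exchange measurements with the Laisk method. Implements the
    forward Farquhar-von Caemmerer-Berry (FvCB) model of net assimilation
    versus chloroplastic CO2 with smooth co-limitation and mesophyll
    conductance coupling, the classical linear-intersection Laisk
    estimator, and a nonlinear estimator that fits the full FvCB model to
    all light-response curves jointly by maximum likelihood. Includes
    temperature scaling (Brooks-Farquhar gamma-star polynomial,
    macromolecular rate theory for Vcmax and Jmax, Arrhenius for Rubisco
    kinetic constants), Monte Carlo propagation of gas-analyser
    measurement noise, and simulation sweeps that quantify the bias of the
    linear estimator across temperatures and CO2 ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
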