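Package: gephase
Title: Two-State Pseudo-Spin Model of Triacylglycerol Melting and Crystal Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field and Monte Carlo tools for the two-state ("g-e")
    pseudo-spin model of the saturated triacylglycerol solid-liquid phase
    transition. The model maps hydrocarbon chain melting onto an Ising model
    in a temperature-dependent field, yielding a spin-reorientation
    temperature T*, a mean-field critical temperature Tc = zJ/kB, and
    discontinuous, critical or crossover behaviour depending on their order.
    Provides the mean-field self-consistency solver with stable, metastable
    and unstable branches, spinodal location, transition enthalpies, a
    chain-length parameterization of the critical point, a trilaurin
    calibration, a modified Vogel-Fulcher-Tammann lifetime model for the
    superheated metastable state (the basis of fat "crystal memory"),
    Metropolis Monte Carlo simulation with exact-enumeration oracles, a
    synthetic generator for labeled holding time-temperature memory data,
    and a command-line interface.
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
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
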