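Package: kgating
Title: Ion Permeation and Gating Analysis for Potassium Channel Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis for potassium-channel gating studies:
    counting of ion and water permeation events through the selectivity
    filter and conversion to single-channel currents, classification of
    S0-S4 binding-site occupancy (ion, water, vacant), kernel-density ion
    distributions along the pore axis treated as approximate free-energy
    profiles, HOLE-style pore radius profiles, activation-gate order
    parameters, partial-least-squares functional mode analysis of the
    gate-filter coupling, and replica-level bootstrap confidence
    intervals.  Ships a synthetic knock-on channel generator with
    ground-truth event logs so the whole pipeline is testable without
    molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
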