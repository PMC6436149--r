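Package: hydrotraits
Title: Plant Hydraulic Trait Analysis from Vulnerability, Pressure-Volume
    and Anatomical Measurements
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of tree hydraulic traits from raw
    laboratory and field measurement series. Fits exponential-sigmoid
    xylem vulnerability and stomatal-closure curves and derives P12, P50
    and P88 response thresholds; performs pressure-volume analysis of
    leaf water relations (osmotic potential at full saturation, turgor
    loss point, cell-wall elasticity); computes conduit anatomical
    indices including the hydraulically weighted diameter and conduit
    wall reinforcement; normalizes hydraulic conductance measurements
    into specific conductivities and native embolism levels; summarizes
    stomatal operating traits (maximum conductance, minimum leaf water
    potential, closure thresholds, safety margins); and applies the
    assumption-gated two-sample testing procedure used in tree
    ecophysiology (Kolmogorov-Smirnov and Levene checks choosing between
    Student's and Welch's t-test). Includes seeded synthetic-data
    generators emulating each measurement type so every pipeline stage
    can be validated by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
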