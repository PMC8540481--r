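Package: ahmt
Title: Automated Hydrodynamic Preparation of Calibration Solutions in Capillary Electrophoresis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Plans, simulates and evaluates in-instrument preparation of
    calibration solutions with the pressure system of a capillary
    electrophoresis (CE) instrument. Provides a time-pressure dilution
    scheduler under a constant pressure-time budget with instrument
    constraints, a Hagen-Poiseuille capillary flow and volume model, a timed
    method-sequence builder with reagent accounting, volume-weighted mixture
    composition, a synthetic electropherogram generator with known ground
    truth, internal-standard calibration on time-corrected peak areas with
    1/x-weighted regression and standardized-residual outlier screening, and
    Deming errors-in-variables regression for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
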