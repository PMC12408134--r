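Package: redquant
Title: Free and Total Drug Quantification from Rapid Equilibrium Dialysis
    LC-MS/MS Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying free, protein-bound, and total drug
    concentrations in plasma from rapid equilibrium dialysis (RED)
    experiments analyzed by targeted LC-MS/MS. Implements the RED
    volume-partition mass balance that back-calculates original plasma
    concentrations from dialysis chamber measurements, dual matrix-matched
    calibration with 1/x-weighted linear regression and ICH M10 curve
    acceptance, and the full ICH M10 bioanalytical validation statistics
    suite (accuracy, precision, matrix effect, selectivity, carry-over,
    stability, reinjection reproducibility, workflow repeatability, and
    spike-before/after recovery). A synthetic-data module simulates binding
    equilibrium, sample preparation volume chains, instrument response with
    proportional and additive noise, matrix-lot effects, injection
    carry-over, and pharmacokinetic time courses, so the complete pipeline
    can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
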