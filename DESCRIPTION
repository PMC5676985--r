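Package: thermocal
Title: Radiometric Calibration and Contrast Enhancement for Uncooled UAV
    Thermal Imagery
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with imagery from uncooled (TEC-less)
    microbolometer thermal cameras flown on unmanned aerial vehicles.
    Fits temperature-calibration models that map the sensor's digital
    response and the microbolometer temperature to object temperature
    (linear, bivariate polynomial, and single-hidden-layer
    backpropagation neural network variants), provides residual
    diagnostics for model selection, applies fitted models to raw
    frames, and implements Wallis local-contrast filtering so that
    low-contrast thermal scenes become usable for tie-point detection
    in structure-from-motion pipelines. Includes ground-control-point
    accuracy summaries, paired field-versus-product temperature
    validation statistics, and synthetic-data generators emulating a
    blackbody calibration campaign and low-contrast overlapping scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    lmtest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Regression, QualityControl
RoxygenNote: 7.3.3
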