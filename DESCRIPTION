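Package: shellcal
Title: Pteropod Shell Transparency as an Ocean Acidification Bioindicator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration and inversion of thecosome pteropod shell
    transparency as a bioindicator of ocean acidification exposure.
    Solves the seawater carbonate system (DIC-TA or pH-TA pairs) for
    pCO2 and aragonite saturation state; scores shell transparency from
    greyscale micrographs; fits the seasonal power-law calibration of
    transparency against saturation state with a duration correction;
    inverts observed transparency into intensity-duration exposure
    envelopes; computes Q10-normalised respiration rates; and screens
    expression matrices for saturation-state-correlated biomarker genes.
    Includes synthetic-data generators emulating the seasonal exposure
    design, so the whole chain is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    mgcv,
    minpack.lm,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
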