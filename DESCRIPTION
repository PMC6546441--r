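Package: wingcrypsis
Title: Calibrated Wing Colorimetry and Background-Choice Inference for
    Seasonally Polyphenic Butterflies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies seasonal crypsis in butterfly wings from calibrated
    scans: landmark-transect colour sampling, CIE-xyY chromaticity conversion,
    Euclidean chromaticity-distance scores for pattern-element contrast and
    background matching, and binomial mixed-model inference (crossed random
    intercepts, BIC backward elimination, likelihood-ratio and parametric
    bootstrap tests, Tukey-adjusted post hoc contrasts) on background-choice
    and activity behaviour.  Includes a synthetic-data module that generates
    wing images and behavioural cohort series with known ground truth, and an
    end-to-end pipeline with a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lme4,
    emmeans,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
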