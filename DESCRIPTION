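Package: antseep
Title: Methane Micro-Seepage Analysis for Continuously Monitored Ant Nests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing continuous in-situ methane (CH4) and
    delta-13C-CH4 records from red wood-ant nests together with fixed-camera
    activity monitoring and environmental covariates. Provides difference-image
    ant-activity estimation with mutual-information registration and per-sensor
    polynomial calibration; robust CH4 / delta-13C anomaly detection
    (median + k*MAD) with coincidence windows; Keeling-plot source-signature
    estimation; weather principal components with sequential-ANOVA regression;
    additive time-series decomposition; lagged cross-correlation; harmonic
    earth-tide series; 2-D Gaussian kernel density of earthquake epicentres;
    and a synthetic-campaign generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
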