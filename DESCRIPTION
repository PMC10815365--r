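Package: dateqi
Title: Quality-Index Modelling and VIS-NIR Chemometric Calibration for
    Fresh Dates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for postharvest quality analysis of fresh (Khalal-stage)
    date fruit. Computes CIELAB colour metrics (total colour difference and
    browning index), aggregates min-max normalized physical and sensory
    attributes into a composite quality index, and fits an exponential
    shelf-life decay model. Provides VIS-NIR spectral preprocessing (scan
    averaging, absorbance conversion, Savitzky-Golay second derivative) and
    chemometric calibration by NIPALS partial least squares regression and a
    single-hidden-layer neural network, with k-fold cross-validation metrics
    (RMSEC, RMSECV, R squared). A synthetic fruit-cohort generator with
    storage-condition trajectories and Gaussian absorption-band spectra makes
    the whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    jsonlite,
    minpack.lm,
    nnet,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
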