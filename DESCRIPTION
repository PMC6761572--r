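Package: pulsedecode
Title: Decoding Pulsatile Transcription-Factor Dynamics at Target Gene Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of how pulsatile transcription-factor dynamics are decoded
    by target gene promoters in single cells. Provides square-wave drug dosing
    regimens, synthetic single-cell fluorescence trace generation, the
    post-segmentation trace-processing pipeline (background subtraction, gap
    interpolation, smoothing, normalization, pulse-count quality control), a
    delayed Hill-function promoter-activation model with dose-response
    construction and multi-start nonlinear least-squares fitting, promoter
    activation metrics (responder classification, timing, magnitude, rate,
    matched cumulative-input rate comparisons), k-means clustering of activation
    traces under the correlation distance, frequency-filter classification
    (all-pass, band-pass, low-pass), and geminin-reporter cell-cycle outcome
    scoring.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
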