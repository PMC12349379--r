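Package: pupilprep
Title: Preprocessing of Multimodal Pupillometry Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A preprocessing pipeline for pupil diameter time series recorded
    alongside lower-rate facial-expression metrics on a shared multimodal
    export (wide CSV, one timestamp column, modalities interleaved on their
    own sampling grids). Provides physiological range filtering, two-stage
    outlier removal (dilation-speed thresholding via the median absolute
    deviation, then moving-average local-deviation thresholding),
    shape-preserving piecewise cubic Hermite (PCHIP) upsampling to a
    millisecond grid with masking of reconstructions spanning long gaps,
    binocular alignment with cross-eye regression imputation, baseline-window
    detection and baseline-relative normalization, bin-average downsampling to
    the facial stream's rate, and full-outer-join integration. Includes a
    synthetic recording generator with labelled blink, occlusion and
    out-of-range artifacts for validation, and a holdout harness for comparing
    interpolation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    pracma,
    withr
Config/testthat/edition: 3
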