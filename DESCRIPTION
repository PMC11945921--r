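Package: ppgcaps
Title: Non-Invasive Blood Glucose Estimation from Photoplethysmography
    with Sparse Capsule Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating blood glucose level (BGL, mmol/L) from
    photoplethysmography (PPG) pulse waveforms. Provides a seeded synthetic
    PPG cohort generator with a documented monotone coupling between glucose
    and pulse morphology, moving-average and Savitzky-Golay preprocessing,
    an eight-family feature extractor (autoregressive spectrum, Teager-Kaiser
    energy, heart-rate statistics, spectral entropy, log energy, pulse
    transit time, peak-to-peak interval, pulse amplitude), a deep sparse
    capsule network regressor with dynamic routing and a sparse-filtering
    objective, convolutional baselines with self-attention, and a glucose
    regression evaluation battery (MAE, MSE, RMSE, MAPE, R-squared, MARD,
    Bland-Altman agreement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
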