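Package: cufflessbp
Title: Cuff-Less Blood Pressure Estimation from ECG, PPG and BCG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: End-to-end estimation of systolic and diastolic blood pressure
    from synchronized electrocardiogram (ECG), photoplethysmogram (PPG) and
    ballistocardiogram (BCG) recordings. Provides a synthetic multi-channel
    cardiovascular signal generator with known ground truth, Butterworth
    band-pass preprocessing with resampling and sliding-window segmentation,
    a 1-D convolutional network with bidirectional gated recurrent units and
    feed-forward attention trained by Adam with early stopping, a pulse
    transit time multiple linear regression baseline built on Pan-Tompkins
    R-peak, BCG J-peak and PPG first-derivative fiducial detection, and a
    clinical evaluation suite (RMSE/MAE/R2, Bland-Altman limits of agreement,
    AAMI criteria, BHS grading, attention heat-map section arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
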