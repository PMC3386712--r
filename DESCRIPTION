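Package: imudetect
Title: Activity and Inactivity Detection for Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Segmentation of body-worn inertial measurement unit (IMU)
    streams into active and static periods. Implements nine detectors
    operating on triaxial accelerometer and gyroscope signals: magnitude
    based (moving variance, acceleration magnitude, angular rate energy,
    stance hypothesis optimal, filtered rectifier), spectrum based (framed
    spectrum and long-term spectral envelope) and memory based
    (graph-theoretic and Parzen-estimated CUSUM change detectors). Includes
    a synthesizer of accelerometer and gyroscope signals mimicking basic
    activities of daily living with exact ground-truth markers, per-sample
    evaluation metrics (accuracy, phi correlation, ROC/AUC), per-signal
    grid-search optimization of detector parameters, and a Monte-Carlo
    benchmarking driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
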