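Package: ecgmi
Title: Real-Time Myocardial Infarction Detection from Single-Lead Wearable ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing and machine-learning pipeline for detecting
    myocardial infarction (ST-segment elevation and T-wave inversion) from a
    single-lead wearable ECG stream. Provides a synthetic ECG generator with
    wearable noise models and a 10-bit ADC emulation, digital filtering and
    median-cascade baseline-wander correction, undecimated dyadic wavelet
    R-peak detection and fiducial-point delineation, a linear isoelectric-line
    versus ST-segment classifier over 10-second sliding windows, quadratic
    time-frequency distributions (Wigner-Ville, spectrogram, extended modified
    B-distribution), time-, frequency- and joint (t,f)-domain feature
    extraction with ROC/AUC screening, and five-fold cross-validated SVM and
    KNN classifiers for the two binary detection tasks, plus a buffered
    10-second real-time decision loop with pluggable alert sinks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
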