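Package: drowsyhrv
Title: Driver Drowsiness Detection from PPG-Derived Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects driver drowsiness from raw photoplethysmography (PPG)
    recordings. Implements the full processing chain: first-order differential
    artifact suppression and pulse-peak detection, peak-to-peak interval
    extraction, 7 Hz cubic-spline resampling of the heart rate variability
    (HRV) tachogram, FFT-based band powers and the LF/HF ratio, an eight-level
    Symlet-3 discrete wavelet decomposition yielding a 43-value feature vector
    (Shannon entropy, mean, variance, kurtosis per level plus multiscale
    spectral slopes), ROC-area feature ranking with independent t-tests, and a
    support vector machine classifier evaluated by leave-one-out
    cross-validation. A synthetic-data module generates ground-truthed
    interbeat-interval series, PPG waveforms and PERCLOS traces so every stage
    is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
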