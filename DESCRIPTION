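Package: pttsaw
Title: Detection and Quantification of Sawtooth Clock-Skew Artifacts in
    Pulse Transit Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a non-physiological sawtooth artifact that
    appears in beat-to-beat pulse transit time (PTT) computed from patient
    monitor ECG and photoplethysmography (PPG) channels. Provides a
    mechanistic dual-clock simulator of paired ECG/PPG recordings with
    ground-truth beat times and PTT, a PTT extraction pipeline (R-peak
    detection, steepest-ascent pulse arrival, 4 Hz cubic-spline
    resampling), power-spectral quantification and dominant-frequency
    classification, a de-shape short-time Fourier transform with ridge
    extraction, cohort time-frequency averaging, and period-synchronous
    template subtraction for removing the artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
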