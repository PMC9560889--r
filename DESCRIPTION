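Package: wptgc
Title: Time-Frequency Nonlinear Granger Causality via Wavelet Packets and
    Polynomial NARX Models
Version: 0.1.0
Authors@R:
    person("wptgc", "developers", email = "wptgc@example.org", role = c("aut", "cre"))
Description: Directed, time-resolved coupling analysis for paired
    physiological time series such as simultaneous EEG and EMG recordings.
    Signals are decomposed into narrow frequency bands with a periodized
    Coiflets wavelet packet transform, and nonlinear Granger causality is
    estimated per band in sliding windows from polynomial (linear plus
    quadratic) NARX models identified by forward-regression orthogonal
    least squares with the error-reduction-ratio criterion. Provides a
    preprocessing chain for raw recordings, synthetic ground-truth
    generators, surrogate-based significance thresholds, band and period
    summaries, group statistics, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
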