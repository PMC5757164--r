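Package: merbeta
Title: Beta-Band Power Spectral Estimation for Intraoperative
    Microelectrode Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for selecting a real-time beta-band (13-35 Hz) power
    estimator for microelectrode recordings acquired during deep brain
    stimulation implantation surgery. Provides a seeded synthetic
    multi-unit-activity recording generator, RMS-based stability-segment
    selection, envelope extraction by rectification and low-pass filtering,
    eight power spectral density estimators (periodogram, Welch with 0.5/1/1.5 s
    Hamming windows, Thomson multitaper with NW = 2 and 6, Burg autoregressive
    models of order 4 and 15) on a common 0.1 Hz frequency grid, beta-band
    summary statistics, and a Friedman rank test with Tukey-style pairwise
    comparisons plus a computation-time harness to pick the fastest
    statistically indistinguishable estimator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
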