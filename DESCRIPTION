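Package: digilamp
Title: Digital Single-Molecule Amplification Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for digital (partitioned) isothermal
    amplification experiments such as digital RT-LAMP on microfluidic
    devices. Estimates template concentration from positive-well counts by
    Poisson (most-probable-number) statistics with ln-scale uncertainty,
    compares digital efficiency between reaction conditions, computes
    standardized differences and minimum replicate numbers for resolving
    efficiency differences in digital and multi-molecule formats, extracts
    time-to-positive from real-time fluorescence traces, models analytical
    sensitivity and limit of detection under a Poisson-Bernoulli model, and
    simulates single-molecule amplification with independent fate
    (efficiency) and rate (time) parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
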