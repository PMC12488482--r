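Package: apcpulse
Title: Incoherent Feedforward-Loop Dynamics of Transient APC/C
    Inactivation with Single-Cell Biosensor Trace Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the incoherent feedforward loop in which mitogen
    stimulation rapidly activates mTOR-mediated phosphorylation of the
    APC/C coactivator CDH1 while delayed protein-phosphatase activity
    reverses it, producing a transient, partial pulse of APC/C
    inactivation during cell-cycle entry from quiescence. Provides a
    five-variable Hill-kinetics ODE model with perturbation scenarios
    (rapamycin, phosphatase inhibition, non-phosphorylatable CDH1), a
    synthetic single-cell biosensor trace generator with lognormal
    cell-to-cell variability and multiplicative measurement noise, and
    the trace analytics used on live-cell degron-reporter data: windowed
    slope fits, the MG132 slope-ratio percent-inactivation statistic,
    transient/sustained trace classification, median-trace divergence
    timing, and CDK2-based cycling-cell classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
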