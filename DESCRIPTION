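Package: pathflow
Title: Turnaround-Time, Backlog and Workload Analysis for Pathology
    Laboratory Case Flows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare the diagnostic efficiency of two pathology
    laboratory workflows (conventional light microscopy versus digital
    pathology on whole-slide images) from case-level receipt and report
    dates.  Implements turnaround-time summaries and two-sample
    comparisons (Welch t and Mann-Whitney U with exact enumeration for
    small samples), a sweep-line daily pending-cases census per
    pathologist, a workload calendar relative to theoretical daily
    diagnostic capacity with year-over-year reduction estimates, and an
    exploratory equipment cost model with depreciation and discounting.
    A calibrated synthetic cohort generator reproduces the distributional
    structure of a two-year biopsy case flow so the whole pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
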