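Package: crcrecur
Title: Microsimulation of Colorectal Cancer Recurrence and Post-Surgical Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of recurrence and follow-up after
    curative resection of colorectal cancer. A continuous-time disease
    progression submodel assigns each patient latent times of earliest
    detectability, loss of resectability, and symptom onset; a discrete-time
    (3-month cycle) Markov submodel overlays scheduled surveillance testing,
    symptomatic interval detection, curative or palliative re-treatment, and
    background mortality. Includes an iterative grid-search calibration engine
    for the disease-progression parameters, one-way deterministic sensitivity
    analysis with common random numbers, and packaged scenarios reproducing the
    intensive and minimal follow-up arms of a classic surveillance trial.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
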