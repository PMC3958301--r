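Package: seizlink
Title: Data-Reduction Strategies for Wireless EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation of transmission strategies for wireless
    electroencephalography (EEG) seizure-detection systems. Implements three
    sensor-side data-reduction branches (raw transmission, compressive sensing
    with sparse binary measurement matrices, and low-complexity time-domain
    feature extraction), a 16-bit uniform quantizer with an i.i.d. bit-flip
    channel model, block-sparse Bayesian and l1 reconstruction solvers, an
    operation-count cost model for the feature extractors, a support vector
    machine seizure detector evaluated with leave-one-record-out
    cross-validation and event-based metrics, and a seeded synthetic EEG
    generator with EDF and plain-text annotation input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
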