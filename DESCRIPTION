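Package: pocnet
Title: Queueing-Location Models for Point-of-Care Viral Load Testing Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning hub-and-spoke sample-referral networks for
    HIV viral-load testing in a county health system. Combines steady-state
    M/M/s queueing (Erlang-C waits for point-of-care hubs, two-stage queues
    for central laboratories) with an exact capacitated facility-location
    solver that selects point-of-care hub sites and the clinic-to-site
    referral network minimizing demand-weighted batching and transport
    time. Includes turnaround-time decomposition into batching, transport
    and waiting components, scenario comparison, one-way sensitivity
    sweeps, a seeded synthetic county generator, a discrete-event
    simulation cross-check for the queueing formulas, and CSV/JSON/GeoJSON
    input-output with a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Rcpp,
    geosphere
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
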