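Package: seatwbv
Title: Seat-Suspension Dynamics and Whole-Body Vibration Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing occupational whole-body vibration (WBV) of
    seated machine operators. Implements a two-mass lumped-parameter model of
    a suspension seat (state-space construction, triangular-pulse time-domain
    response, displacement transmissibility, undamped natural frequencies,
    damping ratio), an ISO 2631-1 style dosimetry pipeline (Wk/Wd frequency
    weighting, weighted RMS, A(8) daily-exposure normalization, vibration
    dose value VDV) with classification against the Brazilian NHO-09
    decision criteria, a calibrated synthetic generator for cabin-vibration
    signals with shock transients, and campaign-level exceedance reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
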