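Package: srvpulse
Title: Time-Resolved Doppler OCT Analysis of Spontaneous Retinal Venous Pulsation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses time-resolved Doppler optical coherence
    tomography (DOCT) recordings of spontaneous retinal venous pulsation (SRVP).
    Provides a synthetic phantom generator for complex-valued OCT B-scan
    sequences of a partially collapsing retinal vein (with optional dual-channel
    acquisition and SLO-like en-face video), phase-difference tomogram
    computation with bulk-phase correction, automated segmentation of the
    dynamic lumen, pulsatile diameter/area/flow time series with cardiac-cycle
    detection, dual-location pulse-delay and flow-conservation analysis, and
    ROI-based pulsatile intensity tracking. Results are returned as tibbles
    with broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
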