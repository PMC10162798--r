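Package: opercal
Title: Event Modulation and Spatial Analysis of Calcium Imaging in Operant Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for one-photon calcium-imaging recordings made
    while animals perform operant conditioning tasks. Classifies neurons as
    significantly modulated around behavioral events (lever presses, reward
    delivery, lever extension) with a baseline-percentile, consecutive-bin
    peri-event criterion; identifies spatially tuned neurons with a
    Skaggs-style spatial-information score against a circular-shift shuffle
    null on a 15 x 15 occupancy grid; and measures place-field
    center-of-mass shifts between lever-switch epochs. Ships a fully seeded
    synthetic subsystem (fixed-ratio, lever-switch, two-lever delay and
    non-contingent session simulators, biased random-walk position tracks,
    GCaMP-like transient traces with ground-truth tuning labels) so every
    stage of the pipeline is verifiable by ground-truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
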