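Package: fnirsloc
Title: Sensor-Location Analysis for Forehead fNIRS Cognitive-Workload Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates forehead functional near-infrared spectroscopy (fNIRS)
    recordings under a 2-back/rest block design and runs the full
    cognitive-workload classification pipeline over them: session screening,
    Butterworth band-pass and moving-average filtering, optical-density and
    modified Beer-Lambert conversion to hemoglobin concentration changes,
    overlapping-window segmentation, per-channel statistical feature
    extraction, Relief and sequential-forward-selection feature selection,
    nested ten-fold cross-validated linear support-vector-machine
    classification per forehead sensing location, and two-sample t-test
    comparison of each partial sensing location against whole-forehead
    sensing. Ships the published per-subject accuracy table as a fixture so
    the summary statistics and significance pattern can be recomputed
    exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
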