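Package: afibscreen
Title: Single-Measurement Atrial Fibrillation Screening from Oscillometric
    Pulse Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects atrial fibrillation from the pulse-to-pulse intervals
    captured during a single oscillometric blood-pressure measurement.
    Provides a seeded rhythm simulator (sinus rhythm, atrial fibrillation,
    premature contractions, missed-pulse artifacts), synthesis of
    oscillometric pressure pulse waveforms with peak detection,
    distributional interval features including the clustered standard
    deviation, an AdaBoost.M1 ensemble of shallow decision trees with
    portable JSON serialization, and the diagnostic-accuracy statistics of
    cuff-based screening studies (sensitivity and specificity with Wilson
    score intervals, McNemar's paired test, Pearson chi-square subgroup
    comparison, the irregularity index), plus a command-line pipeline tying
    simulation, training, classification and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
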