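Package: stresstrace
Title: Wearable Stress Detection from Photoplethysmography and Electrodermal Activity
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A minute-block stress classification pipeline for laboratory
    psychophysiology sessions. Reads raw photoplethysmography (PPG) and
    electrodermal activity (EDA) traces, resamples them to analysis rates,
    detects pulse upstrokes with a derivative-based beat detector, extracts
    inter-beat intervals with physiological validity filtering, computes
    per-minute heart-rate and skin-conductance features normalized against a
    seated resting baseline, trains a two-feature linear stress classifier by
    stochastic gradient descent, and scores block-level decisions with
    signal-detection-theory metrics (hits, misses, false alarms, correct
    rejections). Includes a seeded simulator of Trier-Social-Stress-Test
    structured sessions with ground-truth beat times so that every stage of
    the pipeline can be tested end to end without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
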