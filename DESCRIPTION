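Package: keyfatigue
Title: Mental Fatigue Detection from Keystroke Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects mental fatigue from natural typing patterns. Extracts
    per-key timing features (hold, flight, inter-key and inter-release
    latencies) from keystroke event streams, embeds fixed-length typing
    sequences with a recurrent (LSTM) typing-pattern backbone, adapts the
    frozen backbone to the fatigue-detection task with a triplet-loss
    distance-metric-learning head under a leave-one-participant-out
    protocol, and monitors session sequences with a CUSUM quick-change
    detector calibrated by false-detection, non-detection and detection-
    delay curves. Ships a synthetic typist simulator so the full pipeline
    is testable without any keystroke database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    randomForest,
    caret
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
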