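Package: lmradapt
Title: Adaptive Locomotion-Mode Recognition from Neuromuscular-Mechanical Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-dependent locomotion-mode recognition for powered
    lower-limb prostheses from fused surface-EMG and load-cell features,
    with three unsupervised classifier-adaptation strategies for concept
    drift: entropy-based self-training, learning-from-testing-data (LIFT),
    and transductive SVM. Includes a synthetic gait-signal simulator with
    gradual and abrupt drift schedules, evaluation metrics (static-state
    accuracy, missed transitions), session-level experiment harnesses, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
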