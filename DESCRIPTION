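Package: facemimic
Title: Geometric Facial-Expression Features and Closed-Loop Emotion Mimicry Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for closed-loop emotion-mimicry biofeedback built on
    geometric features of 478-point 3D face-mesh landmarks. Computes
    neutral-reference distance ratios and planar angles from landmark frames,
    trains and applies a small dense network that collapses the six basic
    emotions plus neutral onto a positive/negative output, runs the windowed
    feedback session engine with retry queueing, validates the two-process
    command handshake, and computes the study statistics (confusion-matrix
    metrics, try-again repetition rates with Hazen quartiles, feature-space
    PCA). A synthetic face-landmark generator with emotion-dependent
    deformations makes every component testable without external image
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
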