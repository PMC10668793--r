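Package: shssd
Title: Lightweight Sheep-Head Detection, Tracking and Line-Crossing Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A single-shot sheep-head detector (SH-SSD) built from a
    triple-attention enhanced MobileNetV3-style backbone, an independent
    feature-branch neck with spatial pyramid pooling, and decoupled
    prediction heads, together with the full dynamic-counting pipeline
    around it: SimOTA-style dynamic sample matching for training, a
    DeepSort-style multi-object tracker (Kalman filter plus Hungarian
    assignment), and a line-crossing counter. Includes PASCAL-VOC XML
    input/output, COCO-style average-precision evaluation, a parameter
    auditor, and a seeded synthetic corridor-scene generator so that
    every stage of the pipeline is testable without field footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
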