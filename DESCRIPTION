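Package: ambientpain
Title: Behavior Markers and Pain-Day Classification from Ambient Smart-Home Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying daily behavior from passive ambient sensor
    event streams (passive-infrared motion and magnetic door sensors) in
    single-occupant smart homes, and for detecting days affected by pain from
    those behaviors. Provides an event-log data model with day segmentation
    and pain/pain-free labeling, a calibrated synthetic routine generator with
    injectable pain perturbations, rule-based activity annotation with
    visitor detection and room-to-room traversal timing, extraction of a
    550-entry statistical behavior-marker block plus schedule-regularity and
    circadian-rhythm-strength markers, and an evaluation stage with
    group-aware cross-validated random-forest classification, regression-tree
    correlation, an unsupervised isolation-forest baseline, and
    information-gain marker ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
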