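Package: tonguemap
Title: Point-Mapping Segmentation of Abnormal Regions on the Dorsal Tongue Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patch-classification and point-mapping pipeline for detecting
    abnormal regions on photographs of the dorsal tongue surface. Photographs
    are divided into small square crop images, each crop is classified as
    abnormal, normal or other (non-tongue) mucosa by a pluggable 3-class
    patch classifier, and an overlapping grid of classified tiles is rendered
    as a colour-dot point-mapping segmentation. The package includes the full
    evaluation stack (one-vs-rest confusion-matrix metrics, ROC/AUC,
    point-count intersection-over-union metrics and PASCAL-VOC average
    precision), a deterministic texture-feature baseline classifier, a small
    trainable convolutional network, and a procedural generator of
    tongue-like images with exact per-pixel class masks so that every stage
    of the pipeline can be exercised end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
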