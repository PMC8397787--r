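Package: oralscope
Title: Oral Lesion Photograph Classification with Centered-Capture
    Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for five-class classification of smartphone photographs
    of the oral cavity (normal mucosa, aphthous ulcer, low-risk and
    high-risk oral potentially malignant disorders, cancer). Implements a
    centered region-of-interest preprocessing chain, a rotation and
    offset-center resampling scheme that expands and rebalances training
    sets without zero padding, a compact convolutional classifier with a
    1x1-convolution, batch-normalization and global-average-pooling head
    emitting log probabilities, a patient-disjoint training harness with
    cross-validation, macro-averaged multiclass metrics with DeLong
    confidence intervals for one-versus-rest AUC, and class-activation-map
    visualization. A synthetic oral-image generator provides labeled data
    with the geometric and statistical structure the pipeline assumes, so
    the whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
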