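Package: hazelcount
Title: Tiled-Inference Counting of Hazelnut Female Flowers in High-Resolution Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Vision-based pipeline for counting very small, low-contrast
    objects (hazelnut female flowers, "glomerules") in high-resolution
    whole-plant images. Provides square image tiling with edge padding and
    exact coordinate transforms, conversion of binary annotation masks into
    normalized bounding-box labels, detection-metric evaluation (IoU,
    precision, recall, interpolated AP and mAP@50-95), confidence-filtered
    per-tile detection with a pluggable detector contract, per-side and
    per-plant count aggregation, and regression-based bias correction with
    the associated error metrics (MAE, MAPE, R-squared). A synthetic scene
    generator and a noise-configurable oracle detector make the whole
    pipeline testable without any trained network or field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
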