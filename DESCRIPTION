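Package: WSLTiles
Title: Tiled Two-Stage Detection and Evaluation of White Spot Lesions in
    Intra-Oral Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detector-agnostic implementation of a tooth-to-lesion tiled
    inference pipeline for locating white spot lesions (early enamel
    demineralization) on high-resolution intra-oral photographs. A fast
    tooth-localization stage on a proportionally resized image defines a
    full-resolution crop that is scanned with overlapping 640x640 windows;
    per-tile and holistic detections are remapped to the original frame and
    merged by non-maximum suppression. Includes the full evaluation suite
    (pixel-wise Cohen's kappa, COCO-style 101-point average precision,
    mAP@0.5:0.95, F1-over-IoU curves, bootstrap confidence intervals),
    dataset-geometry analyses (box-area statistics, COCO size classes,
    location heatmaps, crown-coverage fractions), gradient-free score-CAM
    explainability against a pluggable detector contract, a classical
    blob-based reference detector, YOLO-txt and COCO-JSON annotation I/O,
    and a seeded synthetic intra-oral photograph generator so the whole
    pipeline is testable end-to-end without trained network weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
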