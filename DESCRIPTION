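Package: woodmorph
Title: Morphometry of Macerated Wood Fibers and Vessels from Instance
    Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies macerated wood cells (fibers and vessels) from
    instance-segmentation output produced by any external backend: per-cell
    skeleton length via Zhang-Suen thinning and longest-path extraction,
    width via the exact Euclidean distance transform, contour area, and
    micrometer calibration, with border-touching cells excluded. Includes
    readers and writers for VGG Image Annotator JSON, YOLO segmentation
    labels and per-instance mask images; COCO-style instance-level
    evaluation (precision, recall, F1, mAP 0.5-0.95, PR and F1-confidence
    curves); two-group comparison statistics; tiling of large slide scans
    with cross-tile deduplication; and a seeded generator of synthetic
    macerated-slide scenes with exact per-instance ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
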