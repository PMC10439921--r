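Package: fnascreen
Title: Adequacy Screening of Fine-Needle-Aspiration Slides from Follicular-Cluster Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening the adequacy of thyroid fine-needle-aspiration
    (FNA) slide images from follicular-cluster detections. Implements the
    patch-based tiling pipeline (256x256 patches with 50% overlap, a 1%-area
    positivity rule, union stitching back to full-frame detection masks), a
    detection ensemble that intersects two detectors' outputs pixel-wise to
    suppress false positives, one-pixel-overlap matching with
    precision/recall/F1 and whole-image IOU (with the degenerate-image
    exclusion rule), the auto-weighted multi-task loss numerics used for
    patch classifiers, hierarchical (patient-level then image-level)
    bootstrap resampling of slides, slide-adequacy classification with
    user-threshold sweeps, precision-recall AUC and max-F1 selection, and a
    synthetic-data generator emulating the study structure (7 groups of 33
    background + 8 follicular images from 6 patients) with simulated
    detectors of controllable error character.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
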