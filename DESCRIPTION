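Package: fishdet
Title: Transformer-Enhanced Anchor-Free Detection of Fish Species with
    Class-Aware Wise-IoU Losses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying class-imbalance-aware training of
    anchor-free single-stage fish-species detectors at desk scale.
    Implements the Wise-IoU v1/v3 bounding-box regression losses with a
    dynamic outlier-degree gradient gain, a class-aware reweighting of the
    classification, distribution-focal and box-regression objectives for
    long-tailed species data, a configurable CSP-style backbone with
    depth-rescaled C2f stages and transformer blocks in the final backbone
    stage and neck, exact trainable-parameter accounting for all presets, a
    task-aligned target assigner and seedable SGD training loop, COCO-style
    mean-average-precision evaluation with frequency-stratified reporting,
    and a reproducible generator of synthetic long-tailed underwater scenes
    with YOLO-format and COCO-format annotation I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
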