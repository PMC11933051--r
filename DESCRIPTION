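Package: pestnet
Title: Lightweight Re-Parameterized Detection Networks for Forestry Pest Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, analyses, compresses and evaluates lightweight anchor-free
    object detectors for forestry pest imagery. Provides the building blocks of
    an improved YOLOv8-style network (HGStem, re-parameterizable RepConv and
    RepLightConv, dense-aggregation Rep-HGBlocks, GSConv/VoVGSCSP slim-neck
    modules, and a dynamic detection-head tower with scale-, spatial- and
    task-aware attention), exact structural re-parameterization of multi-branch
    blocks into single fused convolutions, layer-adaptive magnitude (LAMP)
    channel pruning towards a FLOPs speed-up target, COCO-style detection
    metrics (precision, recall, AP, mAP at IoU 0.5:0.95, confusion matrices),
    a synthetic 29-class pest-scene generator with YOLO-format labels, and a
    small CPU training harness for smoke-scale experiments. Parameter and FLOP
    accounting reproduces the architecture tables of the model family.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
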