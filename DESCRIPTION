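Package: sonolite
Title: Lightweight Dual-Frequency Detection of Free Fluid in FAST Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a lightweight anchor-free detector for free-fluid
    screening in Focused Assessment with Sonography for Trauma (FAST)
    examinations. The backbone splits features into high- and low-frequency
    streams with octave-convolution cross-fusion after every scale; the neck
    builds a single pyramid-pooled global fusion feature at stride 8 and
    feeds it back to all pyramid levels; the head is a decoupled single-class
    YOLOX-style head trained with SimOTA dynamic assignment and an
    IoU/cross-entropy composite loss. The package ships its own CPU tensor
    engine (forward and backward), an analytic parameter/FLOPs profiler with
    a calibrated counting convention, a seeded synthetic speckle-phantom
    generator with COCO-style annotation I/O and Mosaic/MixUp/horizontal-flip
    augmentation, a COCO-dialect evaluator (precision/recall/F1 at IoU 0.5
    and 0.75, mAP@50:95), a 5-fold cross-validation harness, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
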