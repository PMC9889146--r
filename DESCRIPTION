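Package: echoplane
Title: Standard-Plane Recognition in Fetal Echocardiography with an
    SIoU-Trained Single-Stage Detector
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects anatomical structures of the fetal heart in
    ultrasound-like grayscale images with a configurable anchor-based
    single-stage convolutional detector and classifies images into the
    five standard screening planes (4CH, LVOT, RVOT, 3VV, 3VT) from the
    detected structure set.  Implements the composite detection loss
    (binary cross-entropy classification, IoU-supervised objectness, and
    the SIoU bounding-box regression loss with its angle, distance and
    shape cost terms), conv+batch-norm fusion for inference, greedy
    non-maximum suppression, a full evaluation battery (per-class average
    precision, mAP, positive predictive value, sensitivity, specificity,
    F1, accuracy, and McNemar paired-rater comparison), and a seeded
    generator of schematic speckle-noise ultrasound images with
    bounding-box annotations for training, testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
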