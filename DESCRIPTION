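Package: edgebcs
Title: Lightweight Detection Networks for Beef-Cattle Body Condition Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, profiles, trains and evaluates a lightweight single-stage
    detector for image-based beef-cattle body condition scoring (BCS) from the
    tailhead region. Implements coordinate attention, star-operation texture
    blocks (TASM), a position-sensitive gated-fusion neck (PSFF), an efficient
    grouped detection head (EGDH), focal+global feature distillation losses, a
    layerwise complexity profiler (parameters, GFLOPs, FP16 checkpoint size),
    dataset-construction rules (frame downsampling, motion-blur augmentation,
    animal-level splitting), a synthetic fixture generator, and the standard
    detection metric stack (IoU, NMS, precision/recall, AP, mAP). Includes a
    small reverse-mode automatic-differentiation core with compiled convolution
    kernels so the networks are trainable on CPU at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
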