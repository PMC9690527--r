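Package: omsas
Title: Osteosarcoma MRI Segmentation with an Attention-Condenser Residual Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for binary tumor segmentation of 2-D MRI slices, built
    around ACRNet, a lightweight encoder-decoder convolutional network that
    combines depthwise-separable residual blocks with attention condensers
    (squeeze-excite style channel gating on a spatially condensed embedding).
    The package covers the full pipeline: intensity-based preprocessing
    (mean-threshold binarization, hole filling, effective-region cropping,
    min-max normalization), dihedral-group data augmentation, Tversky-loss
    training with patient-level splits and k-fold cross-validation,
    test-time-augmentation inference fused by per-pixel majority vote, a
    confusion-matrix metric panel (accuracy, precision, recall, F1, IoU,
    DSC), and a synthetic MRI-like phantom generator so every stage can be
    exercised without clinical data. The network, including forward and
    backward passes and Adam optimization, is implemented in R on top of
    vectorized matrix arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
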