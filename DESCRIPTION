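Package: hprnet
Title: Hierarchical Pyramidal Residual Networks for ECG Heartbeat Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Heartbeat-level electrocardiogram (ECG) arrhythmia classification with
    a hierarchical pyramidal one-dimensional residual network built from residual
    extraction blocks, together with multi-level L1-magnitude unstructured pruning,
    closed-form parameter and FLOP accounting, cross-validated training and
    evaluation, 1D Grad-CAM saliency, wavelet soft-threshold denoising, WFDB record
    ingestion with AAMI symbol mapping, and a synthetic beat generator so that the
    full pipeline runs without any data download. The network forward and backward
    passes are implemented on top of BLAS matrix products (im2col convolution), so
    no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
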