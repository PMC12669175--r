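Package: msmseg
Title: Multi-Scale Multi-Scan State-Space Segmentation of 3-D Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-wise segmentation of small bright lesions in
    anisotropic 3-D brain MRI, built around a selective state-space sequence
    model (Mamba-style) with a multi-scale multi-scan serialization of the
    volume into complementary 1-D sequences. Provides multi-scanner intensity
    harmonization against a reference scan, geometric standardization
    (resampling, cropping, padding), an encoder-decoder network with
    depthwise-separable 3-D convolutions and deep supervision trained with a
    combined Dice and cross-entropy objective, spacing-aware evaluation
    metrics including the 95th-percentile Hausdorff distance, a reproducible
    synthetic lesion-phantom generator, and a command-line interface covering
    the full generate/preprocess/train/predict/evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
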