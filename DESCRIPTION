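Package: moeseg
Title: Explainable Mixture-of-Experts Segmentation of Vascular Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable mixture-of-experts framework for delineating the
    lumen and outer wall of abdominal aortic aneurysms on axial grayscale
    slices. Three specialized U-Net experts (differing in loss function,
    initialization and data partition) are combined by an error-learning
    router and a robust per-pixel weight router into a spatially adaptive
    fused prediction; gradient-based attention maps and per-expert error
    maps expose the routing decisions. Includes a seeded vascular phantom
    generator with paired ground-truth masks, periodic B-spline contour
    correction, the full overlap and boundary metric suite (Dice, IoU,
    HD95, confusion-matrix metrics), and clinical cross-sectional
    measurements (lumen areas, maximum hydraulic diameter, RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    RNifti,
    stats,
    grDevices,
    utils,
    splines
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
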