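Package: evogmd
Title: Evolutionary Optimization of Gabor Filter Banks for Skin Lesion
    Texture Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact, interpretable texture descriptors for binary
    dermoscopic skin-lesion classification by evolving the parameters of a
    multi-scale Gabor filter bank with differential evolution (DE/best/1/bin).
    Each candidate bank is scored by the stratified cross-validated error of a
    linear support vector machine on mean/standard-deviation response features
    extracted from masked lesion regions. Includes ROI preprocessing (grayscale
    conversion, rescaling, mask cropping), a seeded synthetic generator of
    two-class directional textures with elliptical lesion masks so the full
    pipeline runs without external data, the two-stage optimize/evaluate
    experimental protocol, and confusion-matrix metrics with degenerate-model
    (majority collapse) diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
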