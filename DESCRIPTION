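Package: acromir
Title: Content-Based Retrieval of Acromion Morphology in Shoulder MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A content-based image retrieval (CBIR) pipeline for typing the
    acromion (flat, curved, hooked, convex) on sagittal shoulder MR slices.
    Computes histogram-of-oriented-gradients (HOG) and grid local-binary-pattern
    (LBP) texture descriptors plus pluggable deep-feature blocks, reduces each
    block with greedy minimum-redundancy maximum-relevance (mRMR) feature
    selection, fuses the reduced blocks into a normalized searchable index, and
    ranks database images against a query by Euclidean distance or peak
    signal-to-noise ratio (PSNR). Retrieval quality is scored with interpolated
    11-point precision-recall curves and average precision, per class and over
    the whole database. Includes a synthetic acromion-phantom generator so the
    full pipeline is testable end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
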