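Package: findfoci
Title: Trainable Focus (Spot) Detection for Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of bright, diffraction-limited foci in 2D or 3D
    fluorescence microscopy images by local-maximum identification,
    uphill-gradient peak expansion and saddle-based merging of
    insignificant peaks. Includes point-set comparison statistics
    (Jaccard, Recall, F1) for agreement between annotators and
    algorithms, alignment of manual click annotations to their true
    local maxima, an exhaustive grid-search optimiser that trains
    detection parameters against annotated images (with staged caching
    and multi-image score aggregation), and a synthetic nucleus scene
    generator with simulated annotators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
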