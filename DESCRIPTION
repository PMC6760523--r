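Package: ctcscope
Title: Automated Fluorescence Microscopy Pipeline for Circulating Tumor
    Cell Enumeration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image-analysis stack for automated enumeration of circulating
    tumor cells (CTCs) captured on a microfiltration membrane and imaged by
    multi-channel widefield fluorescence microscopy. Provides a quantitative
    CMOS camera model (quantum efficiency, shot noise, read/dark noise,
    noise-equivalent photon floor, object-space pixel geometry), a
    rule-driven multi-channel classification and counting pipeline
    (median filtering, window/level contrast stretch, per-phenotype
    classification-mask arithmetic, Otsu thresholding, connected-component
    extraction and size gating), a brightness-based coarse/fine autofocus
    search, tile-grid planning and abutting-tile stitching for whole-membrane
    panoramas, and a ground-truthed synthetic membrane simulator (virtual
    microscope) used to exercise the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
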