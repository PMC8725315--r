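Package: stalkmorph
Title: Cross-Section Morphometry of Plant Stalks from Stained Section Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Semi-automated phenotyping of plant stalk cross-sections from
    stained section images. Converts calibrated RGB images (TIFF/PNG) of
    pith-filled (maize, sorghum) or hollow (wheat, Arabidopsis) stalks into
    binary masks by Otsu or local adaptive thresholding, segments the whole
    section and the pith or lumen, removes speck artifacts by area-gated
    morphological smoothing, and measures the headline phenotypes: major and
    minor diameter (axis-endpoint or Feret convention), mean rind thickness
    from boundary-to-boundary shortest distances, cross-sectional areas, and
    vascular bundle counts with file-based manual corrections. Extracted
    boundaries can be exported in world (millimeter) coordinates as a finite
    element preprocessor sketch script or as CSV/GeoJSON/SVG. A seeded
    synthetic phantom generator with exact analytic ground truth makes the
    whole pipeline verifiable without physical specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
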