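Package: fiberarch
Title: Quantification of Collagen Fiber Architecture, Strain, and Stained Area in Tissue Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing fibrotic from regenerative tissue
    organization in 2-D micrographs. Implements intensity-gradient fiber
    orientation detection with doubled-angle circular statistics (mean vector
    length, mean angle, angle kurtosis), individual-fiber tracing with
    per-fiber morphometrics (length, width, straightness, box density),
    assembly of a multi-feature collagen-architecture panel reduced by
    principal component analysis to a fibrosis-regeneration axis, least-squares
    estimation of a homogeneous deformation gradient from tracked fiducial
    markers with Green-Lagrange strain conversion, percent-positive-area
    quantification for fluorescence images, and a synthetic-data generator
    providing ground-truth fiber fields, marker grids, area images, and
    feature panels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
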