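Package: fisheyetree
Title: Tree Height Measurement from Fisheye Images with an Equidistant
    Projection Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monocular photogrammetric estimation of standing-tree heights
    from single fisheye photographs. Implements an equidistant-projection
    fisheye camera model with per-axis distortion coefficients (pixels per
    radian), checkerboard calibration of those coefficients by per-corner
    solution and averaging, conversion of detected tree bounding boxes into
    metric heights via back-projection of the top/bottom edge midpoints,
    single-class detection metrics (precision, recall, F1, average
    precision), mosaic augmentation for annotated images, and a synthetic
    scene generator that produces fisheye-projected checkerboards and tree
    silhouettes with exact ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
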