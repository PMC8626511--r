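Package: fmpvselect
Title: Stable Feature-Subset Selection for Random-Forest Histology Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects small, stable vectors of hand-crafted pixel features
    (colorimetric spaces, Gabor, Haralick GLCM, rotation-invariant uniform
    LBP, local mean and variance) for weighted random-forest segmentation of
    stained histological images. Implements a size-limited brute-force search
    over feature combinations, the feature Median Position Value (fMPV)
    stability criterion computed on F-score-sorted combination tables at
    feature, family and space scales, a two-step selection procedure (family
    pre-selection followed by iterative feature aggregation under two-fold
    swap validation), a seeded generator of synthetic DAB-stained tissue
    images with exact four-class ground truth, and tiled application of a
    trained model to large images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    parallel,
    png,
    ranger,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
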