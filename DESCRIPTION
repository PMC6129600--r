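Package: footprintr
Title: Automated Arch-Height Morphometry of 2D Plantar Footprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts geometric and Gabor-wavelet shape features from binary
    toeless plantar footprint images (area, perimeter, circularity, second
    wavelet moment, orientation-histogram entropy, contour curvature and mean
    bending energy), computes the Cavanagh-Rodgers arch index by automated
    trisection of the print, and scores arch height with a fitted linear model
    on perimeter and mean bending energy, classifying feet as high, normal or
    low arch under either cut-off scheme. Includes a synthetic-footprint
    generator with controllable medial-arch depth for validation, a batch
    driver producing a feature table CSV, and an ordinary-least-squares
    calibration utility for refitting the arch-height model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
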