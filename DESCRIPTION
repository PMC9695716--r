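Package: leafnitro
Title: Leaf Nitrogen Prediction from Calibration-Board Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates rice leaf nitrogen content (g/kg) from visible-light
    images of leaves photographed on a calibration board of known square size.
    Provides leaf segmentation and board detection, pixel-to-physical area
    calibration, G-channel colour statistics, a hybrid Gaussian radial basis
    function + partial least-squares regression model tuned by a genetic
    procedure, linear and general-regression (Nadaraya-Watson) baselines,
    regression evaluation statistics, and a synthetic scene/dataset generator
    with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
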