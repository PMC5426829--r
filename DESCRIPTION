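Package: glanceCount
Title: Fruit Counting by Count Regression on Simulated Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Yield estimation by counting fruit in RGB images at a glance,
    without detection. Provides a parametric synthetic tomato-scene generator
    with exact count labels (cluttered green/brown backgrounds, occlusion,
    shadow and illumination variation), a modified Inception-ResNet count
    regression network with a compact CPU training engine (Xavier
    initialization, Adam, mean-squared-error cost, dropout, batch
    normalization, exponential-moving-average evaluation weights), an
    area-based counting baseline (YCbCr thresholding, mathematical morphology,
    calibrated per-fruit area) and a shallow-network baseline, plus the
    per-image relative-accuracy, MSE/RMSE and predicted-versus-actual
    regression statistics used to compare the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
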