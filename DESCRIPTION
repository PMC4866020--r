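Package: rtcamoa
Title: Mode-of-Action Classification from Real-Time Cell Analysis Response Curves
Version: 0.1.0
Authors@R: person("rtcamoa", "developers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for classifying the mode of action (MOA) of chemical
    compounds from impedance-based real-time cell analysis (RTCA)
    time-concentration response curves (TCRCs). Provides cell-index
    normalization and cubic-spline resampling onto an hourly grid,
    multilevel discrete wavelet featurization with coarse-to-fine
    coefficient pruning, Gaussian-kernel support vector machine and
    feedforward neural network classifiers, repeated stratified
    random-split evaluation, tree-structured multi-cluster
    classification, dose-response-curve statistics with data-driven
    time-window selection, and a synthetic TCRC generator for
    end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
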