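Package: planefusion
Title: Residual CNN Feature Fusion for Fetal Ultrasound Standard-Plane Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and shape inference of two compact residual
    convolutional network architectures for maternal-fetal ultrasound
    standard-plane classification, stochastic-gradient training with
    global-average-pooling deep-feature extraction, Gaussian-process
    Bayesian optimization of training hyperparameters with the expected
    improvement acquisition, generalized normal distribution optimization
    (GNDO) wrapper feature selection with a binary-cross-entropy threshold,
    serial fusion of selected feature blocks, shallow neural-network
    classification with a confusion-matrix metric suite, and a paired
    t-test for classifier comparison. Includes a synthetic speckle-image
    and planted-feature generator so the full pipeline is exercisable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    EBImage,
    lhs,
    pROC,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
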