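Package: breathdx
Title: Breath VOC and Capnogram Analysis for Asthma Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multichannel exhaled-breath records
    for binary asthma classification. Provides a labelled synthetic cohort
    generator (capnogram shape classes, Gaussian volatile-organic-compound
    profiles, sensor noise, triplicate sessions), waveform preprocessing
    (standardization, end-tidal plateau detection, scalar breath features,
    principal component analysis), Gaussian deconvolution of VOC profiles
    with asthmatic-versus-control group comparison, a channel-attention
    neural classifier with capsule dynamic routing trained under a combined
    focal and binary cross-entropy loss, and a cross-validated evaluation
    harness with reference classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    e1071,
    class,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
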