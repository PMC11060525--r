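Package: palynet
Title: Hierarchical Pollen Image Classification and Stratigraphic Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-testable workflow for automated fossil-pollen
    identification and downstream palaeoecological analysis. Small
    convolutional networks are arranged in a taxonomy tree: each node
    classifies a grain image among its own output classes and either emits a
    terminal label, passes the image to a child network, or abstains to the
    parent taxon when its calibrated confidence falls below a threshold.
    Node confidences are calibrated by temperature scaling fitted on
    validation negative log-likelihood. The package ships a procedural
    generator of labelled dark-field grain images spanning the common
    north-eastern American morphotypes (with a tunable fresh-to-fossil
    degradation dial), dataset splitting/balancing/augmentation utilities,
    evaluation surfaces (normalized confusion matrices, average per-class
    accuracy, abstention rates, per-class agreement regressions), and the
    classical pollen-diagram statistics: exotic-marker concentration and
    influx, percentage diagrams, stratigraphically constrained incremental
    sum-of-squares zonation (CONISS) with broken-stick zone selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
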