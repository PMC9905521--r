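Package: chaosbench
Title: Synthetic Dynamical-System Time Series for Chaos Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generator and benchmark for labelled synthetic time series from
    fifteen dynamical systems (chaotic, periodic, quasi-periodic and
    non-periodic), intended as training material for machine-learning models
    that detect chaotic behaviour in empirical signals such as biomedical
    recordings. Ordinary-differential-equation systems (Lorenz, Roessler,
    Halvorsen, Rucklidge, Ueda and seven linear oscillators/damped systems)
    are integrated with an adaptive Dormand-Prince Runge-Kutta 4(5) scheme and
    resampled on an equidistant grid; quasi-periodic signals with irrational
    frequency ratios are evaluated in closed form. Data augmentation
    randomizes initial conditions uniformly. The package also provides
    derivative-based phase-portrait embedding, a reproducible CSV/zip dataset
    layout with a seed manifest, and the chaos-versus-non-chaos validation
    experiments: segmentation, labelling, train/validation/test splits, and
    small LSTM and one-dimensional convolutional classifiers trained with
    Adam, reported as confusion matrices and accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
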