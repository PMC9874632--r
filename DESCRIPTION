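Package: nmrmultiplet
Title: Detection and Classification of Multiplet Signal Regions in 1D 1H NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, point-wise neural sequence labeling, and two-level
    evaluation of multiplet signal regions in one-dimensional 1H NMR spectra.
    Provides a pseudo-Voigt based simulator that produces labeled synthetic
    spectrum segments (seven first-order multiplet classes plus baseline,
    with phase, baseline and rooftop distortions and Gaussian noise), a
    Conv1D/bidirectional-LSTM point-wise classifier with its own
    reverse-mode training engine, point-wise confusion-matrix metrics and
    object-wise intersection-over-union average-precision metrics, and a
    reproducible simulate-train-predict-evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'lineshape.R'
    'multiplet.R'
    'simulate.R'
    'dataset.R'
    'network.R'
    'train.R'
    'predict.R'
    'evaluate.R'
    'io.R'
    'pipeline.R'
    'zzz.R'
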