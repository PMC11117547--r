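Package: mmgforce
Title: Dynamic Muscle Force Estimation from Multichannel Mechanomyography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating dynamic skeletal muscle force from
    multichannel mechanomyographic (MMG) recordings. Quantifies inter-muscle
    cross-talk with lag-weighted normalized cross-correlation, extracts a
    25-feature bank (time, frequency, time-frequency and nonlinear
    descriptors) over sliding windows, screens features against the force
    target by grey relational analysis, and regresses force with a single
    layer LSTM network whose hyper-parameters are tuned by an improved grey
    wolf optimizer. Includes baseline models (back-propagation neural
    network, epsilon-SVR), a synthetic-recording generator with a known
    mixing (cross-talk) structure and force-activation law, and experiment
    drivers comparing feature combinations and models.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
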