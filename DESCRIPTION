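Package: modmindy
Title: Modulated Mesoscale Neural Dynamics Models from Regime-Labeled Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits biologically constrained nonlinear state-space network models
    of mesoscale brain activity in which a baseline excitatory/inhibitory
    connectivity matrix is scaled element-wise by nonnegative rank-1 modulation
    matrices, one per labeled dynamical regime (the modulated MINDy
    architecture). Provides the forward generative model, a synthetic-data
    generator with hidden-Markov regime switching for parameter-recovery
    studies, a dual-estimation fitting engine (extended Kalman filtering,
    free-simulation forecasting, backpropagated gradients with NADAM updates
    under sign, sparsity and rank constraints), recovery and reliability
    metrics, and EEG preprocessing utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
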