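Package: sctrnn
Title: Stochastic Continuous-Time Recurrent Networks with Modifiable
    Predictive Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stochastic continuous-time recurrent
    neural networks (S-CTRNN) that learn to predict the mean and variance of
    two-dimensional drawing trajectories.  Two developmental parameters modify
    the predictive-coding loop during learning: the external-contribution
    parameter (mixing raw sensory input with the network's own prediction at
    the input layer) and an aberrant-precision offset applied inside the
    variance readout.  The package provides the synthetic drawing task
    (ellipses and figure-eight shapes at four positions with per-shape sensory
    noise), gradient-based training of weights and per-class initial states
    under a Gaussian negative log-likelihood, closed-loop and reactive
    trajectory generation, initial-state inference for recognizing novel
    trajectories, and evaluation of internal representations via PCA
    embeddings and dynamic-time-warping inner/outer distances, together with
    reproducible parameter-sweep experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
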