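Package: adexfp
Title: Diffusion Approximations and Fokker-Planck Methods for Adaptive
    Exponential Integrate-and-Fire Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state and linear-response statistics of the adaptive
    exponential integrate-and-fire (AdEx) neuron driven by stochastic synaptic
    input.  Implements quasi-static and matched-variance diffusion
    approximations for sub-threshold adaptation and temporally correlated
    synaptic input, a threshold-integration solver for the associated
    one-dimensional Fokker-Planck equation on refinable non-uniform voltage
    meshes (standard Euler, modified Euler with midpoint rule, and modified
    Euler with Simpson's rule schemes), self-consistent coupling of the mean
    adaptation current to the firing rate, and frequency-domain linear
    response: susceptibility curves on coarse logarithmic frequency meshes
    with monotone cubic interpolation, spike-triggered averages by inverse
    FFT, and shared-input spike-train cross-covariances.  A compiled
    forward-Euler Monte Carlo simulator of the exact two-dimensional model
    (homogeneous or Ornstein-Uhlenbeck-modulated Poisson input) with Welch
    cross-spectral and spike-triggered estimators serves as the validation
    oracle for every approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
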