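Package: blochdesign
Title: Physics-Guided Self-Supervised RF Pulse Design via Differentiable Bloch Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Designs magnetic-resonance radiofrequency (RF) pulses by training a
    small multilayer perceptron against a differentiable hard-pulse Bloch
    simulator: the network maps a target magnetization profile to a complex RF
    waveform, the simulator plays the waveform on a grid of spins, and the
    mean-squared profile mismatch is back-propagated through the exact
    rotation-matrix propagation to update the network (physics-guided
    self-supervision). Supports 1D frequency-selective excitation,
    B1-insensitive inversion designed jointly across a peak-amplitude sweep,
    spectral-spatial (water/fat) excitation under an oscillating gradient, and
    2D spatially selective excitation along variable-density spiral-in
    trajectories, plus online adaptation of a converged design to measured
    B0/B1+ field maps through rank-constrained (LoRA) side parameters.
    Includes generators for reference waveforms (hyperbolic-secant, SPSP,
    spirals), analytic target builders, synthetic field-map fixtures, plain-text
    waveform/profile I/O and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
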