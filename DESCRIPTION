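Package: layer4sim
Title: Point-Neuron Simulation of the Layer 4 Mouse V1 Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and simulates an all-point-neuron (leaky integrate-and-fire)
    model of layer 4 of mouse primary visual cortex. Provides the cell-placement and
    like-to-like connectivity rules (distance- and orientation-dependent connection
    probabilities with the four LL/LR/RL/RR rule variants), a linear-nonlinear-Poisson
    filter bank standing in for LGN inputs with retinotopic lasso-subfield wiring,
    traveling-wave background drive, staged synaptic-weight calibration, in-silico
    optogenetic perturbations, a visual stimulus battery (drifting gratings, flashes,
    moving bars, gray screen), and the full suite of visual-physiology response metrics
    (OSI, DSI, F0/F1, lifetime sparsity, CV of ISI, Fano factor, signal/noise
    correlations, optogenetic modulation index, multi-unit activity spectra, LGN input
    fractions and convergence).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
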