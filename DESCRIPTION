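Package: transneuron
Title: Stochastic Diffusive-Memristor Artificial Neuron Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an artificial spiking neuron built around a diffusive
    memristor, in which silver nanoclusters diffuse in a dielectric gap under
    electrical, thermophoretic and Brownian forces, coupled to an RC readout
    circuit.  Provides a seeded Euler-Maruyama integrator for the stochastic
    Langevin model, a deterministic thermo-electric companion model with
    fixed-point, Hopf-bifurcation, hysteresis and basin-of-attraction
    analysis, spike-train statistics (inter-spike intervals, CV1, CV2, Welch
    power spectra, burst segmentation, convex-hull coverage of CV clouds),
    surrogate spike-train generators with known statistics, and reproducible
    experiment drivers for spiking-regime sweeps, frequency selectivity under
    AC drive, and a two-signal voltage/temperature phase comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    mgcv,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
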