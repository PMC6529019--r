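Package: gammalock
Title: Phase Locking and Macroscopic Phase-Resetting Analysis of Coupled
    Gamma-Oscillatory Spiking Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing emergent gamma oscillations in
    excitatory-inhibitory circuits of quadratic integrate-and-fire neurons
    with Lorentzian-distributed excitability.  Provides finite-size spiking
    network simulation, the exact eight-dimensional mean-field reduction
    (firing rate, mean voltage and first-order synapses per population),
    fixed-point and Hopf bifurcation analysis, macroscopic infinitesimal
    phase-resetting curves via the adjoint method with direct-perturbation
    validation, interaction (H) and coupling (G) functions for two weakly,
    bidirectionally delay-coupled circuits, phase-locking mode extraction
    and bifurcation diagrams, delay-differential simulation of the coupled
    sixteen-dimensional reduced system and of twin spiking networks, and
    global phase-resetting curves that expose leader/follower symmetry
    breaking and directional signal transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
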