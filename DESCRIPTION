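Package: aeifnet
Title: Delayed-Conductance Networks of Adaptive Exponential
    Integrate-and-Fire Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of random excitatory/inhibitory
    networks of adaptive exponential integrate-and-fire (AEIF) neurons
    coupled through conductance-based synapses with transmission delays.
    Provides generators for random directed networks with a fixed
    excitatory/inhibitory split, a fixed-step integrator (compiled core)
    for the delayed-coupling dynamics with threshold-and-reset spiking,
    synchronization diagnostics (time-averaged Kuramoto order parameter
    on spike phases, inter-spike-interval coefficient of variation,
    mean firing frequency, mean synaptic input), and orchestration of
    delay-plane parameter sweeps averaged over realizations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
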