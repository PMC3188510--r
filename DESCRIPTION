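Package: hypercolumn
Title: Spiking Ring-Network Model of a Visual Cortical Hypercolumn
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a two-layer orientation hypercolumn
    built from exponential integrate-and-fire neurons on coupled ring
    networks with conductance-based AMPA, NMDA and GABA synapses,
    contrast-tuned thalamic (LGN) Poisson drive and shared-rate
    Ornstein-Uhlenbeck background input. Includes the analysis battery
    for the model's contrast-dependent dynamical regimes: orientation
    tuning and contrast-response fits, the population synchrony measure
    chi and its finite-size scaling, spike and voltage correlograms,
    simulated local field potentials and multi-unit activity with Welch
    spectra and coherence, peristimulus time histograms, single-spike
    perturbation experiments, and delay-embedding chaos diagnostics
    (false nearest neighbors, neighbor divergence, largest Lyapunov
    exponent estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
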