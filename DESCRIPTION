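Package: inexa
Title: Simulation of Coupled Neuronal and Astrocytic Networks on Virtual MEA Cultures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time stochastic simulator of an interacting neuronal and
    astrocytic network on a virtual two-dimensional multielectrode-array (MEA)
    culture. Neurons spike as inhomogeneous Poisson processes coupled through
    Tsodyks-Markram short-term plastic synapses; astrocytes enwrap excitatory
    synapses, follow local IP3/calcium dynamics with threshold-triggered
    gliotransmission, and form a gap-junction network with three-state
    (inactive/active/refractory) whole-cell dynamics that feeds back on the
    neurons through release-probability potentiation and adenosine-like
    depression. Includes spatial topology generation with distance-dependent
    connection rules, a scenario ladder that adds astrocytic signalling in
    stages, and an analysis pipeline: burst detection via the cumulative moving
    average (CMA) of the interspike-interval histogram, pooled-activity spectra
    with border-corrected Gaussian smoothing, neuron-astrocyte
    cross-correlation, and astrocyte activation ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
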