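Package: cahomsim
Title: Cell-Autonomous Calcium Homeostasis in Conductance-Based Hippocampal Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment conductance-based model of a hippocampal CA1
    pyramidal neuron with twelve ion channels, Goldman-Hodgkin-Katz AMPA/NMDA
    receptor synapses, and detailed intracellular calcium handling (radial
    diffusion over concentric annuli, static buffer, SERCA uptake, ER leak and
    plasma-membrane extrusion). Provides the seven standard intrinsic
    measurements (firing rate at 250 pA, spike amplitude, input resistance and
    impedance amplitude/resonance/phase measures), random model populations with
    experimentally bounded validation and pairwise parameter correlations, and
    an integral-control transcription/translation engine that evolves all twelve
    conductances toward a cytosolic calcium target under theta-frequency or
    sharp-wave-ripple afferent drive, including behavioural state-switch
    protocols with robust/plastic classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
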