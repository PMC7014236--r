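Package: snnemg
Title: Spiking Neural Networks with Spike-Timing-Dependent Plasticity for
    EMG Pattern Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of Izhikevich spiking neurons with
    pair-based and triplet-based spike-timing-dependent plasticity (STDP),
    multiplicative soft weight bounds, and an activity-dependent synaptic
    forgetting rule. Provides a two-layer winner-take-all network that
    classifies multi-channel surface-electromyography (EMG) patterns by
    unsupervised or supervised competitive learning, a synthetic
    eight-channel EMG generator with gesture structure and graded effort,
    temporal and rate stimulation protocols for single-neuron coding
    experiments, and scripted experiment pipelines with reproducible,
    seeded simulations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
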