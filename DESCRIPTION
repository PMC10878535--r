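Package: dwsyn
Title: Attractor Neural Networks with Double-Well Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying memory storage in recurrent networks of binary
    neurons whose synapses evolve in a piecewise-quadratic double-well
    potential. Provides the stochastic synapse model (decay toward the wells,
    Hebbian input jumps, Gaussian plasticity noise), a discretized
    master-equation solver for the synaptic weight distribution and its
    input-conditioned variants, a Gaussian mean-field theory of retrieval and
    storage capacity for balanced coding, direct network simulation for
    balanced and sparse coding, signal-to-noise-ratio analysis of the
    binarized weights against matched two-state Markov synapses, and a sweep
    harness with tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
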