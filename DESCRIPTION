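Package: lifbridge
Title: Mapping Leaky Integrate-and-Fire Neurons onto Fixed-Point
    Neuromorphic Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Translates continuous-time leaky integrate-and-fire (LIF)
    point-neuron models, specified in physical units (ms, mV, pA, pF),
    onto the discrete-time fixed-point compartment model used by
    digital neuromorphic hardware, and quantifies the fidelity of the
    translation. Provides the bidirectional parameter and state
    mapping with all quantization and representability checks, an
    exact-integration reference simulator for the continuous model, a
    bit-faithful software emulator of the fixed-point compartment
    update with 23-bit saturation, stimulus generators (constant bias,
    frozen spike tables, Poisson sources), randomly connected
    excitatory/inhibitory network simulation on either backend, and a
    validation layer computing root-mean-square error and Pearson
    correlation between paired runs, including temporal- and
    voltage-precision sweep experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
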