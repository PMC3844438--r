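Package: seqreplay
Title: Sequence Replay in Willshaw Networks with Inhomogeneous Sparseness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of sequence memory in recurrent networks
    of binary neurons with clipped-Hebbian (Willshaw) synapses and
    instantaneous feedback inhibition, when the sparseness of the stored
    patterns varies across the sequence. Provides coding-ratio distributions
    (Gamma, triangular), exact and ensemble statistics of the synaptic
    potentiation probability, a two-variable (hits/false-alarms) mean-field
    model of replay with linear or supralinear feedback inhibition, a full
    binary-network simulator used to validate the mean field, and analysis
    tools for replay success rates, storage capacity, power-law
    capacity-stability trade-offs, and sequence-termination mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
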