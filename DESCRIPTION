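Package: stdfa
Title: Spike-Train Level Direct Feedback Alignment for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of multi-layer leaky integrate-and-fire
    spiking neural networks with spike-train level direct feedback alignment
    (ST-DFA). Provides discrete-time LIF/SRM neuron dynamics, exact and online
    computation of spike-train level post-synaptic potentials (S-PSP), the
    hardware-friendly power-of-2 feedback variant in which error feedback is
    realised by arithmetic shifts (ST-DFA-2), a symmetric-weight backpropagation
    baseline, fixed-point arithmetic emulation matching digital-hardware bit
    widths, Poisson rate encoders and synthetic rate-coded classification tasks,
    an IDX image container reader, and an experiment harness with deterministic,
    seed-controlled training runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
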