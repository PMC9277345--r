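Package: izhnode
Title: Fixed-Point Izhikevich Network Simulation and Latency-Based
    Performance Modeling of a Neuromorphic Compute Node
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A functional twin of a single-chip neuromorphic compute node for
    spiking neural network simulation. Provides bit-faithful emulation of the
    node's 40-bit signed fixed-point (s16.23) arithmetic, forward-Euler
    Izhikevich neuron pipelines with an adaptive Runge-Kutta-Fehlberg
    verification oracle, event-driven ring-buffer synaptic delivery with a
    valid-timestamp invalidation scheme, a Create/Connect/Simulate engine with
    deterministic spike recording, a latency-based analytical performance
    model (acceleration factors and performance-loss decomposition), a
    programmatic two-population benchmark network generator, and a spike-train
    statistical validation pipeline (firing rates, coefficient of variation of
    inter-spike intervals, pairwise Pearson correlation, and two-sample
    Kolmogorov-Smirnov comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
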