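Package: relmass
Title: Stimulus-Equivalence Simulation with Projective-Simulation Agents,
    Network Enhancement, and Relational Density Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates matching-to-sample (MTS) stimulus-equivalence
    experiments with a projective-simulation reinforcement-learning agent
    whose memory is a weighted directed graph of stimulus clips. Derived
    (symmetry, transitivity, equivalence) relations are consolidated by a
    Network Enhancement diffusion step that can run either at the end of
    training or at every mastery point. Relational Density Theory
    instrumentation records per-class time series of four relational-volume
    measures (true and empirical nodal distance, class size, number of
    relations), three relational-density measures (mean transition
    probability, class accuracy, mean edge weight), and their product,
    relational mass. Includes a cohort experiment runner replicating a
    five-phase, four-class linear training study under both Network
    Enhancement scheduling conditions, JSON experiment configuration,
    and exports for trial logs, metric series, edge lists, weight
    matrices, and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
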