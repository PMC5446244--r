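Package: striatseq
Title: Variable-Speed Neural Sequence Generation in Striatal Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for models of sparse sequential
    activity in recurrently connected inhibitory circuits such as the
    striatum. Implements a winner-take-all rate network in which short-term
    synaptic depression paces the hand-off of activity between clusters of
    medium spiny neurons, with the sequence speed controlled by the level of
    tonic excitatory input; an anti-Hebbian plasticity rule that lets
    time-varying "tutoring" input carve sequences into initially random
    inhibitory connectivity; an excitatory network with shared inhibition
    that reduces to the same effective model; and a clustered network of
    exponential integrate-and-fire neurons with per-synapse depression and
    anti-Hebbian spike-timing-dependent plasticity. Includes closed-form
    switch-time theory, input-protocol generators, sequence-extraction and
    weight-structure analysis, and a config-driven experiment runner with
    plain-text artifact bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
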