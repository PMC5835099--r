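Package: tristdp
Title: Event-Driven Three-Factor (Dopamine-Modulated) STDP Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates spiking neural networks whose synapses learn with a
    dopamine-modulated, trace-based spike-timing-dependent plasticity (STDP)
    rule. Pair-based STDP writes to a per-synapse eligibility trace, and an
    exponentially decaying dopamine concentration gates the conversion of
    eligibility into actual weight change. Synapses are updated lazily, only
    when a pre-synaptic spike arrives, using closed-form integration of the
    inter-event dynamics; a dense clock-driven integrator of the same dynamics
    is included as a ground-truth reference. Ships current-based leaky
    integrate-and-fire neurons, Poisson and scripted spike sources, delayed
    delivery through a ring buffer, and ready-made reinforcement and
    Pavlovian-conditioning experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
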