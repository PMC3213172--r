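Package: delayq
Title: Queueing Analysis and Exact Simulation of Distributed Transcriptional Delay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the effect of randomly distributed protein
    production delay on transcriptional signaling. Maps delayed protein
    production onto a transient M/G/infinity queue and provides the
    signaling-time (first time K mature proteins exist) density, moments and
    closed forms, together with an exact stochastic simulation algorithm for
    reaction networks with delayed products. Includes analyses of signaling
    cascades, coherent and incoherent feedforward loops, repressor switches,
    and the delayed negative-feedback (degrade-and-fire) oscillator, plus a
    reproducible config-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
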