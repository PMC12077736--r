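Package: lampresim
Title: Stochastic Life Cycle Simulation for Anadromous Lampreys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An annual-step, stage- and age-structured stochastic population
    simulator for anadromous lampreys (larvae, transformers, ocean juveniles,
    in-river adults, spawners). Demographic stochasticity enters through
    binomial, negative-binomial and beta draws with moment-matched parameters;
    egg and larval survival are density dependent via Beverton-Holt functions.
    Management operators cover downstream/upstream barriers, transformer and
    adult translocation, and hatchery releases. Includes a multi-replicate
    simulation engine with burn-in, a five-scenario management comparison,
    Latin hypercube global sensitivity designs over 44 life cycle parameters,
    and repeated random-forest permutation importance, plus YAML/JSON
    configuration loading, CSV output with run manifests, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    optparse,
    parallel,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
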