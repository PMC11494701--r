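Package: bnnsim
Title: Simulation of Sequestration-Based Biomolecular Neural Networks with Shared Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action simulator and analysis toolkit for biomolecular
    perceptrons and feed-forward biomolecular neural networks built from
    sigma factors, antisigma proteins, and a shared limited pool of core RNA
    polymerase. Provides exact algebraic and ODE-integration steady-state
    solvers, the asymptotic ReLU (AReLU) and saturated ReLU (ASReLU)
    activation-function limits, resource-competition analysis, response maps
    over input grids, decision-boundary extraction, interference and
    ideal-design deviation metrics, named presets for the published network
    designs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
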