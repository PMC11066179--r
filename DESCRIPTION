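Package: fieldcode
Title: Simulation, Decoding and Evolutionary Optimization of
    One-Dimensional Multi-Field Spatial Codes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and simulates rate-based network models of
    hippocampal place codes and entorhinal grid codes on a linear track:
    fixed multi-field codes organized in hierarchical line attractors,
    dynamic multi-field codes with gamma-distributed field sizes and
    size-gated lateral connectivity, single-scale single-field line
    attractors, and modular one-dimensional grid codes.  Provides
    threshold-linear rate dynamics, template-matching population-vector
    position decoding, accuracy/energy/robustness metrics, neuron
    drop-out lesioning, input-removal attractor tests, and an
    evolutionary (genetic) optimizer over discretized model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
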