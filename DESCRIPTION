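Package: pathsem
Title: Pathway Perturbation Analysis via Structural Equation Modeling
Version: 0.1.0
Authors@R:
    person("pathsem", "developers", email = "pathsem@example.org",
           role = c("aut", "cre"))
Description: Detects differentially expressed genes with permutation-based
    SAM statistics, ranks perturbed signaling pathways by combining
    over-representation and topological perturbation evidence, extracts and
    prunes directed pathway modules, fits observed-variable linear
    structural equation models to gene expression data by maximum
    likelihood, refines them via modification indices, and compares
    case/control groups through node- and edge-level invariance models
    with likelihood-ratio and Brown's combined tests. Includes a
    simulation module that generates expression matrices from known
    structural models so every pipeline stage is testable offline, and a
    command-line interface orchestrating the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
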