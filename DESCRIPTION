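Package: genecircuit
Title: Design, Simulation and Characterization of Genetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An object-oriented abstraction for synthetic genetic networks in
    which operators map regulator concentrations to gene-product synthesis
    rates through Hill-type transfer functions. Networks are simulated
    deterministically (ODE) or stochastically (Gillespie direct method) under
    growth-rate dilution, assays produce tidy kinetic measurement tables, and
    a staged characterization workflow fits source, receiver, one-input and
    two-input operator parameters from dose-response time courses. Designs can
    be saved as JSON, exported as regulation graphs (GraphML/DOT) and as
    SBOL3-style hierarchical design documents, and measurements managed in a
    local tidy datastore.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
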