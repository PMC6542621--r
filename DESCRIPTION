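Package: memorg
Title: Input-Dependent Formation and Organization of Memory Representations
    in Plastic Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates rate-coded recurrent neuronal networks whose excitatory
    synapses evolve under correlation-based Hebbian plasticity combined with
    homeostatic synaptic scaling, optionally complemented by a gated inhibitory
    plasticity rule, and analyzes the resulting memory representations.  A
    reduced two-population equilibrium framework (adiabatic weight elimination,
    nullcline and fixed-point analysis) classifies the functional organization
    of two cell assemblies - no memory, discrimination, sequence, association,
    or bistable - and maps these organizations as phase diagrams over external
    inputs and over the model parameters (target rate, inhibition level,
    activation-threshold position).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
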