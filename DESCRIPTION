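Package: elopt
Title: Energy Layer Optimization for Pencil-Beam-Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing the number of energy layers delivered in
    intensity-modulated proton therapy (IMPT) plans while preserving plan
    quality. Treatment planning with dose-volume-histogram objectives and a
    minimum-monitor-unit constraint is posed as a mixed-integer program in
    which continuous variables carry spot intensities and binary variables
    select energy layers. The model is solved by iterative convex relaxation
    combined with the alternating direction method of multipliers; the binary
    layer-selection subproblem is a quadratic unconstrained binary
    optimization (QUBO) handled by exact enumeration, simulated annealing, or
    a statevector variational-quantum (QAOA-style) routine. The package also
    provides a practical workflow for choosing the number of active layers, a
    delivery-time model (energy switching, spot spill, spot switching), fully
    synthetic digital-phantom cases for testing, and Matrix Market based case
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
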