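Package: switchgrade
Title: Combinatorial Screening of Gene Regulatory Networks for Robust
    Bistable Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks small gene regulatory network designs by their capacity
    for robust hysteresis, the behaviour underlying bistable switches in
    synthetic biology.  Networks are annotated signed digraphs with a fixed
    sum-then-multiply interaction algebra.  For each node the package
    enumerates the realizable inequality regions of its kinetic parameters
    (a factor graph), takes the product parameter graph, and computes
    wall-labelled state transition graphs and Morse graphs that identify
    stable states cell by cell.  Hysteresis, perturbed-hysteresis and
    robustness scores are evaluated exactly over monotone paths of the
    input node's factor graph.  A companion Hill-function ODE layer builds
    smooth models from the same parameters and validates switching by
    pseudo-arclength continuation with saddle-node detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    igraph,
    jsonlite,
    quadprog,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
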