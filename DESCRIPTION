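Package: cbnet
Title: Circuit-Breaking Analysis of Regulatory Network Fixed Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fixed-point and bifurcation analysis of ordinary differential
    equation models of intracellular regulation networks via the
    circuit-breaking algorithm. The interaction graph of a model is
    decomposed into strongly connected components, all elementary feedback
    circuits are enumerated and broken at a minimal circuit-covering vertex
    set, and a one-dimensional circuit-characteristic is constructed whose
    zeros are the fixed-point coordinates of the leading variable. The slope
    of the characteristic is related to Jacobian determinants, which yields
    a sufficient instability criterion for leading-vertex graphs, and
    parameter sweeps of the characteristic locate saddle-node and Hopf
    bifurcation candidates. Ships ready-made models of hematopoietic
    stem-cell differentiation, the repressilator, and tryptophan regulation
    in Escherichia coli, plus seeded random-model generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
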