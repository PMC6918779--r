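Package: neurovertex
Title: Vertex-Model Simulation of the Growing Neuroepithelial Apical Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the apical surface of a pseudostratified neuroepithelium
    (such as the embryonic mouse neural tube) as a two-dimensional vertex model
    on a growing torus. Cells are polygons whose vertices follow overdamped
    gradient dynamics of an energy with area elasticity, junctional tension and
    perimeter contractility; interkinetic nuclear movement enters through a
    cell-cycle-dependent target area. The engine supports T1 rearrangements,
    length-weighted edge-split cell division, stochastic differentiation with
    apical extrusion, anisotropic global drag on the two torus radii, clone
    tracking and event logging. An analysis layer provides segmented-cell
    geometry descriptors (area, perimeter, neighbour number, elongation,
    orientation), clone-shape statistics, proliferation-rate estimators,
    Lewis-law fits, and ECDF/Kolmogorov-Smirnov scores for screening mechanical
    parameters against experimental geometry tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
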