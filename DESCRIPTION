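Package: somamesh
Title: Repair and Soma Segmentation of Neuronal Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic repair of hole- and cavity-damaged triangular
    surface meshes of intracellularly injected neurons, and automatic
    segmentation of the cell body (soma) from its dendrites. Artifact
    vertices are detected by ray-traced ambient occlusion, an automatic
    threshold is derived from a two-component one-dimensional Gaussian
    mixture at the equiprobable decision boundary, and a closed surface is
    rebuilt from the surviving oriented vertices by an indicator-function
    (Poisson) reconstruction on a regular grid. The soma is separated from
    basal and apical dendrites by a two-step Gaussian-mixture clustering of
    the shape diameter function. Includes mesh comparison metrics
    (vertex-to-surface RMSE and volume-quotient MAQ), PLY/OFF/OBJ/STL input
    and output, and a synthetic neuron-fixture generator with ground-truth
    labels and injectable damage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
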