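Package: patchnet
Title: Patchy-Disc Monte Carlo Simulation and Morphology Analysis of
    Trisymmetric Tile Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional Monte Carlo simulation of trisymmetric
    macromonomers (three-point-star DNA tiles) modelled as hard discs with
    three Kern-Frenkel patches whose binding interfaces switch between a
    bindable "closed" state and a non-bindable "open" state, capturing
    interface flexibility as an entropic control parameter of network
    nucleation and growth. Includes the network-morphology quantification
    stack used to characterise the assemblies: bonded-graph construction,
    island statistics, planar face (polygon) enumeration, network density,
    border ratio and their time series; phase-diagram sweeps over the
    open-state probability, interaction strength and patch width with
    automated state classification (gas, short-like, long-like,
    diffusion-limited aggregation); a synthetic ground-truth generator for
    honeycomb islands, elongated assemblies and AFM-like raster images; and
    an image-analysis pipeline (flattening, segmentation, skeletonization,
    particle-centre detection) that feeds detected centres back into the
    morphology stack.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    igraph,
    EBImage,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
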