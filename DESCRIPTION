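Package: LymphNetQuant
Title: Quantification of 3D Hepatic Lymphatic Vessel Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification of tubular fluorescence networks in 3D
    light-sheet style image volumes, developed for hepatic lymphatic vessels
    imaged around portal tracts. Provides hysteresis thresholding, connected
    component curation, slice-wise concave-hull tissue masking, homotopic 3D
    skeletonization with spacing-aware distance-transform radii, skeleton to
    spatial-graph conversion with iterative refinement, per-segment
    morphometry (inter-branchpoint length and average cross-section area), a
    self-contained Mann-Whitney U test for two-group comparisons, and a
    synthetic phantom generator with exact ground-truth vessel graphs that
    emulates both the ladder-like wild-type network and its rarefied,
    discontinuous mutant counterpart.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, ImageProcessing, Visualization, Network
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LymphNetQuant-package.R'
    'RcppExports.R'
    'graph-io.R'
    'graph.R'
    'methods-accessors.R'
    'morphometry.R'
    'phantom.R'
    'pipeline.R'
    'refine.R'
    'roi.R'
    'segmentation.R'
    'skeleton.R'
    'stats.R'
    'utils.R'
    'volume-io.R'
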