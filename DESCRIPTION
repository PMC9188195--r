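Package: amyquant
Title: Quantification Pipelines for Amyloid Plaque and Microglia Imaging and
    Sorted-Microglia Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification layers
    used in knock-in mouse models of amyloid pathology: 2D fluorescence
    section quantification (median smoothing, local background subtraction,
    binarization, small-object removal, plaque dilation rings, per-ROI marker
    statistics), 3D confocal microglia segmentation (isotropic resampling,
    Gaussian background subtraction, bipartite-threshold random-walker
    segmentation, thickness-based soma seeding with non-maximum suppression,
    geodesic watershed cell assignment, methoxy-X04 content and plaque
    proximity), brain-wide voxelized plaque counting and density over an
    atlas ontology, and the statistical layer for sorted-microglia omics
    (internal-standard normalization, detection filtering, moderated linear
    models, fold-change threshold tests, eigen-weighted single-sample
    gene-set scores, running-sum leading-edge enrichment, hypergeometric
    overlap). A synthetic-data module generates every input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    EBImage,
    RNifti,
    tiff,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
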