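Package: catmtools
Title: Context-Aware Template Matching and Spatial Analysis for
    Crowded Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the positions and orientations of
    nucleosome-like particles in crowded cryo-electron tomograms such as
    chromatin condensates.  Provides parametric disc and rod density
    templates, a synthetic-tomogram simulator with missing-wedge, contrast
    transfer function and noise degradation, exhaustive template matching
    with locally normalized cross-correlation, context-aware template
    matching (CATM) that resolves steric clashes between neighbouring
    particles by pairwise pose optimization, scoring of predicted particle
    sets against ground truth, and downstream spatial statistics of
    condensate organization (interface geometry, contact-graph valence
    entropy, assortativity, density-based clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
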