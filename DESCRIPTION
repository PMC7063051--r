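Package: cryotrace
Title: Protein Backbone Tracing from Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting protein C-alpha backbone traces from
    cryo-EM density maps. Simulates Gaussian-sum density maps and voxel
    label maps from atomic models, normalizes and cubes volumes for a
    cascaded three-stage dilated 3D convolutional segmentation network
    (secondary structure, backbone, C-alpha), traces C-alpha chains
    through the resulting confidence maps with a tabu-search path
    walker, refines the trace graph (path combination, side-chain, loop
    and dead-end removal), re-idealizes alpha-helices about an estimated
    screw axis, and scores predictions against ground truth with
    one-to-one C-alpha matching metrics (RMSD, percentage within 3
    angstroms, false-positive error rate). Reads and writes PDB and
    MRC2014 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    parallel
Config/testthat/edition: 3
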