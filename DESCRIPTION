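Package: nfvm
Title: Vertex-Model Mechanics and Morphometrics of Neural Plate Folding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two- and three-dimensional vertex models of an epithelium
    containing a dispersed subpopulation of apically constricting cells,
    as used to study passive cell elongation and furrow formation during
    neural plate folding. Includes overdamped gradient dynamics and
    quasi-Newton relaxation on polygonal/prismatic cell meshes,
    gyration-tensor cell-shape analysis, label-image morphometrics
    (second-moment aspect ratio and orientation, junction and cytoplasm
    intensities, apical-domain dynamics classification), a synthetic
    tissue and track generator with ground truth, and a registry of
    named in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
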