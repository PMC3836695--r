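Package: cleftsim
Title: Cellular Potts Simulation of Salivary Gland Cleft Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional Glazier-Graner-Hogeweg (Cellular Potts) model
    of cleft progression in the embryonic submandibular salivary gland
    epithelium. Provides a compiled Metropolis lattice engine with contact,
    area, perimeter and focal-point-plasticity energy terms; builders for
    single-cleft and three-cleft organ configurations with named parameter
    presets; a mitosis scheduler; boundary-curvature cleft morphometrics
    (depth, spanning angle, tilt angle) applicable to simulated states and
    segmented label masks; cell-motility tracking; and a parameter-sweep
    pipeline that classifies cleft outcomes and ranks cellular contributors
    by support-vector-machine feature removal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    e1071,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
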