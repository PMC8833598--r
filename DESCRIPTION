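Package: mrtdose
Title: Microbeam Radiotherapy Dose Simulation and Plan Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating microbeam radiotherapy (MRT) treatment
    plans on voxelized phantoms. Generates micrometer-scale peak/valley
    dose distributions from cross-firing conformal microbeam fields with
    a simplified analytic lattice model, reduces the subvoxel dose in each
    CT-scale voxel to a 35-bin dose histogram and an equivalent uniform
    dose (EUD) under the linear quadratic model, converts doses to their
    2 Gy per fraction equivalent (EQD2), and compares plans through
    dose-volume histograms, dose metrics, D98% normalization and
    organ-at-risk constraint reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
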