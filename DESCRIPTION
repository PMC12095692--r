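Package: ligandflow
Title: Ligand-Based Screening, Biophysical Assay Fitting, Binding-Epitope
    Detection, and Membrane-Permeability Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native workflow for characterizing small-molecule
    protein-protein interaction inhibitors. Implements Gaussian shape and
    pharmacophore-color overlap scoring with Tanimoto-Combo ranking for
    ligand-based virtual screening; nonlinear curve fitting for biophysical
    readouts (four-parameter logistic dose-response IC50, microscale
    thermophoresis 1:1 binding isotherms, nanoDSF F350/F330 melting curves,
    saturation-transfer-difference NMR epitope mapping, and
    Henderson-Hasselbalch pKa titrations); interaction-fingerprint based
    detection of ligand-binding epitopes from free-ligand-diffusion
    trajectories; and membrane-permeability prediction from potentials of
    mean force via the solubility-diffusion model with PAMPA calibration.
    Seeded synthetic-data generators emulate each assay so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    igraph,
    minpack.lm,
    signal,
    bio3d,
    pracma,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse,
    withr
Config/testthat/edition: 3
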