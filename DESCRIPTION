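Package: stereoddi
Title: Stereochemistry-Aware Drug-Drug Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions from molecular structure by fusing
    2D topological graph representations with 3D conformer-derived spatial
    features. Molecules are parsed from SMILES and featurised into attributed
    graphs; 3D conformers are generated with OpenBabel, rotation-augmented, and
    encoded through coordinate, centroid-distance and direction-angle pathways.
    A graph-attention encoder with hierarchical self-attention pooling supplies
    the 2D view; a bidirectional cross-attention feature-exchange module aligns
    the two modalities; interaction triples are scored with relation-specific
    bilinear (RESCAL) forms. Training combines a binary cross-entropy main task
    with a multiscale InfoNCE contrastive objective whose weight is linearly
    annealed. Includes drug-level cold-start splitting, ablation switches, a
    synthetic DrugBank-shaped benchmark generator with rule-defined labels and
    E/Z stereoisomer pairs, and a small reverse-mode autodiff engine with an
    AdamW optimiser that the model is trained with.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
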