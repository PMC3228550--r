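Package: epipatch
Title: Conformational B-Cell Epitope Prediction from Antigen Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts conformational (discontinuous) B-cell epitopes on antigen
    surfaces from 3D structures. Surface residues are described by thick surface
    patches (nearest spatial neighbours including interior residues), encoded
    with an adjacent-residue-distance weighting together with relative solvent
    accessibility, evolutionary conservation from PSI-BLAST profiles, secondary
    structure and amino-acid composition, and classified with a balanced
    bootstrap-and-vote random-forest ensemble suited to the heavy class
    imbalance of epitope data. Includes per-structure leave-one-out
    cross-validation with ROC/AUC reporting, distance-distribution statistics
    for epitope versus non-epitope patches, and a deterministic synthetic
    antigen-antibody complex generator for testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
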