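Package: gatddg
Title: Protein Stability Change Prediction from Self-Supervised Graph
    Attention Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts mutation-induced protein stability changes (ddG,
    kcal/mol) from structure. A graph attention encoder over protein
    heavy-atom graphs is pretrained with a self-supervised task: side
    chains are perturbed to rotamers sampled from a rotamer library and
    the encoder learns to predict each perturbed atom's displacement
    from its native position. Pooled per-atom representations of the
    mutated residue and its environment, for wild type and mutant, feed
    a ten-fold ensemble of gradient-boosted regression trees. Includes
    rotamer-based side-chain perturbation, Shrake-Rupley solvent
    accessibility, a reduced Kabsch-Sander secondary-structure
    assigner, synthetic peptide fixtures, and evaluation metrics for
    accuracy and direct/inverse anti-symmetry bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    xgboost,
    stats,
    utils,
    jsonlite
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
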