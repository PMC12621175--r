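Package: clmdesign
Title: Chemical Language Model Pipeline for Nuclear-Receptor Ligand Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a SMILES-based
    chemical language model (CLM) design pipeline for nuclear-receptor
    ligand discovery. Covers corpus standardization and filtering, Morgan
    fingerprint similarity, character-level SMILES tokenization, a stacked
    LSTM language model with two-stage layer-frozen fine-tuning and SMILES
    augmentation, beam-search epoch selection, temperature sampling,
    multi-criteria design prioritization (sampling frequency, template
    similarity, aggregated docking score via an optional external engine),
    chemical-space embedding (truncated SVD + t-SNE), a spiked
    virtual-screening simulation, and a synthetic scaffold-family corpus
    generator so the whole pipeline runs end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with rdkit on PATH as 'python';
    optionally smina and openbabel for the docking adapter.
Config/testthat/edition: 3
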