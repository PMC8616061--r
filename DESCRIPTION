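Package: emplex
Title: EMT Trajectory, Plasticity Energy and Cell-Cell Communication from
    Single-Cell Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of epithelial-mesenchymal transition (EMT)
    progression in single-cell RNA-seq data. Provides recovery-curve (AUC)
    scoring of epithelial and mesenchymal gene signatures, consensus
    clustering with eigengap model selection, soft clustering by symmetric
    nonnegative matrix factorization with transition-cell detection,
    signature-anchored trajectory inference and pseudotime, transcriptional
    diversity and correlation-network single-cell energies (including an EMT
    circuit energy restricted to the signature genes), cluster-level
    ligand-receptor communication probabilities with permutation
    significance and signaling roles, group statistics with one-tailed
    t-tests, and a negative-binomial synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
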