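Package: slimscan
Title: Proteome-Wide Target Prediction for Peptide-Binding Domains and
    Protein Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts proteome-wide targets of modular protein domains
    (SH3-like peptide-binding domains, serine/threonine kinase catalytic
    domains) from experimental motif data.  Converts peptide-library
    signal matrices or phage-display peptide sets into a normalized
    position-specific scoring matrix with substitution-matrix, flat or
    entropy pseudo-counts, scans a target proteome with a bounded sorted
    hit list, annotates hits with per-residue conservation, solvent
    accessibility and disorder tracks, and ranks candidate targets by a
    naive Bayes posterior (optionally PCA-preprocessed) trained on
    gold-standard interaction pairs.  Includes a synthetic-study
    generator with planted motif instances for end-to-end validation,
    stratified cross-validation with ROC/AUC, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    e1071,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
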