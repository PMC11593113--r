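Package: prokphos
Title: Prediction of Prokaryotic Phosphorylation Sites from Peptide Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue-centred peptide windows from prokaryotic protein
    sequences and phosphosite tables, encodes them with eight classical
    sequence descriptors (APAAC, CKSAAP, CTDC, DDE, DistancePair, EAAC, PAAC)
    plus a group-based peptide-similarity score and two contextual channels
    (a small self-attention encoder trained on the user's data and a pluggable
    protein-language-model embedding provider), and scores candidate sites
    with an ensemble of per-feature deep networks whose outputs are combined
    by an integration network.  General O- and N-phosphorylation models can be
    fine-tuned into residue- or species-specific predictors with hidden layers
    frozen.  Includes specificity-anchored decision thresholds, ROC/AUC and
    cross-validation utilities, hypergeometric motif and region enrichment
    tests, attention-derived motif weight matrices, and a synthetic
    phosphoproteome generator with planted kinase-like motifs for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
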