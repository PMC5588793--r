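Package: erpred
Title: Prediction of Endoplasmic Reticulum Resident Proteins from Sequence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sequence-only prediction of endoplasmic reticulum resident
    proteins (ERRPs). Implements six composition-based feature encodings
    (amino acid, dipeptide, pseudo amino acid, and three split amino acid
    composition schemes), a cost-sensitive support vector machine classifier
    with leave-one-out cross-validation, PROSITE-style scanning for
    C-terminal ER-retention signals (KDEL-class and dilysine motifs),
    per-residue enrichment/depletion profiling with bootstrap significance,
    and a seeded synthetic-data generator that plants the compositional and
    motif structure the method exploits. FASTA in, TSV out, with a
    command-line interface for batch prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
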