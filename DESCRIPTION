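Package: transpec
Title: Substrate-Specificity Prediction for Membrane Transport Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of membrane transporter substrate
    specificity. Encodes protein sequences with five fixed-length
    descriptors (amino acid composition, dipeptide composition,
    physico-chemical class composition, averaged AAindex biochemical
    properties, and a summed position-specific scoring matrix profile) and
    their hybrids, trains one-vs-rest RBF support vector machines for seven
    substrate-specific transporter classes plus a non-transporter control
    class, and evaluates them by stratified five-fold cross-validation with
    sensitivity, specificity, accuracy, coverage, Matthews correlation
    coefficient and ROC-AUC. Includes a seeded synthetic-data generator
    with controllable between-class compositional separation, readers and
    writers for FASTA, PSI-BLAST ASCII PSSM and manifest files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
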