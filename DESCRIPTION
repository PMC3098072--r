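Package: gtppred
Title: Prediction of GTP-Interacting Residues, Dipeptides and Tripeptides
    from Sequence and Evolutionary Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level prediction of GTP-binding sites in proteins.
    Builds overlapping fixed-length window patterns around single residues,
    dipeptides and tripeptides, encodes them as one-hot vectors or as
    normalized PSI-BLAST position-specific scoring matrix (PSSM) profiles,
    and trains support-vector or feed-forward neural classifiers.  Includes
    five-fold cross-validation with a full threshold-sweep metric suite
    (sensitivity, specificity, accuracy, precision, F1, Matthews correlation
    coefficient, ROC/AUC and precision-recall curves), residue composition
    analysis, a distance-cutoff structure annotator, a synthetic benchmark
    generator that plants Walker-A-like motifs, and a command-line
    interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    e1071,
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
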