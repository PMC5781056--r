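Package: succpred
Title: Lysine Succinylation Site Prediction from Structural and Evolutionary Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts succinylated lysine residues in protein sequences from
    per-residue evolutionary profiles (PSI-BLAST position-specific scoring
    matrices) and predicted structural tracks (accessible surface area,
    three-state secondary-structure probabilities and four backbone angles).
    Each lysine is described by a 31-residue peptide window with mirror
    padding at protein termini and converted into a 657-component feature
    vector combining raw structural tracks with bigram transition profiles
    of the evolutionary and secondary-structure matrices. The heavily
    imbalanced negative class is reduced by k-nearest-neighbour elimination
    with an incrementally grown neighbourhood, and a radial-basis-function
    support vector machine discriminates modified from unmodified lysines,
    evaluated by stratified n-fold cross-validation (sensitivity,
    specificity, accuracy, Matthews correlation coefficient, AUC). A
    synthetic-data generator emulates all input formats with a tunable
    class-conditional signal so the full pipeline is testable without
    external predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
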