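Package: magqc
Title: Two-Stage Completeness and Contamination Estimation for Genome Bins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality assessment for metagenome-assembled genomes (MAGs) from
    protein-domain count profiles. Stage I estimates completeness and
    contamination from dynamically extracted marker families shared by the
    K nearest reference profiles; stage II refines the estimates with
    regression models trained on count-ratio-histogram (CRH) features.
    Includes the reference-database builder (profile dereplication and
    universal single-copy marker discovery), a ground-truth bin simulator
    with tetranucleotide-signature-matched contaminants, a synthetic
    domain-world generator for end-to-end testing, and an evaluation
    harness with date-based splits and two-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    nnet,
    randomForest,
    e1071,
    glmnet,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
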