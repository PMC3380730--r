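Package: pssmpp
Title: Integrative Sequence Profiles for Heme-Binding Residue Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-only prediction of heme-binding residues from protein
    chains. Parses AAindex1 physicochemical scales and PSI-BLAST ASCII
    position-specific scoring matrices (PSSMs), normalizes property scales to
    zero mean and unit population standard deviation, and builds per-residue
    sliding-window feature vectors: one-hot binary, logistic-scaled PSSM,
    physicochemical property (PP), their concatenation, and the condensed
    integrative PSSMPP profile that couples each PSSM row with selected
    amino-acid scales. Informative scales are chosen by classifier-free AUC
    ranking followed by a greedy forward-selection loop with Pearson
    correlation pruning, assessed by balanced-sampling cross-validation of a
    radial-kernel support vector machine. Includes the full residue-level
    metric suite (accuracy, sensitivity, specificity, precision, MCC, F1,
    ROC/AUC), a planted-signal synthetic data generator for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    yaml,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    pROC,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
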