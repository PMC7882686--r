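Package: rtcp
Title: Reduced-Alphabet Tripeptide and PSSM Features for Transporter Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein sequences (ATP-binding cassette transporter
    versus non-transporter) from a composite feature that joins reduced
    amino-acid-alphabet tripeptide composition (RTC) with a sigmoid-averaged
    summary of PSI-BLAST position-specific scoring matrices (PSSM). Provides
    the six canonical reduced alphabets built from physicochemical
    properties, feature extraction from FASTA and ASCII PSSM files, PCA
    compression, a one-dimensional convolutional network classifier with
    conventional baselines (SVM, naive Bayes, random forest, feed-forward
    network), stratified cross-validation with MCC/F-score/ROC reporting,
    repeated-training stable-misclassification analysis, and a synthetic
    two-class sequence and PSSM generator so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest,
    nnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
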