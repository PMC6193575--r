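Package: gpsuc
Title: Prediction of Lysine Succinylation Sites from Sequence Windows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts lysine succinylation sites in protein sequences from
    41-residue windows centred on candidate lysines. Windows are encoded by
    five complementary schemes (amino-acid composition, one-hot binary,
    twelve AAindex physicochemical scales, PSI-BLAST profile scores, and
    profile-based k-spaced amino-acid pair composition), screened per
    feature with a Wilcoxon rank-sum test, scored by one random-forest
    channel per encoding, and fused into a single probability by logistic
    regression. Includes profile parsing with a deterministic pseudo-profile
    fallback, threshold-dependent and ROC/AUC evaluation with stratified
    cross-validation, compositional-bias analyses around modification
    sites, and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
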