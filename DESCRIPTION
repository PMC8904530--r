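Package: pvpstack
Title: Stacked Ensemble Prediction of Phage Virion Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stacking-based ensemble classifier for phage virion (structural)
    proteins from primary sequence. Thirteen sequence and profile feature
    encoders (amino-acid/dipeptide composition, dipeptide deviation from
    expectation, composition-transition-distribution, pseudo and amphiphilic
    pseudo amino-acid composition, windowed composition, AAindex properties,
    and three PSSM-profile descriptors) feed ten classifier families to build
    a pool of baseline models. Out-of-fold baseline probabilities become
    probabilistic meta-features that are pruned by gradient-boosting
    importance ranking plus a top-k subset sweep and fed to a random-forest
    meta-model. Includes a synthetic sequence/profile generator with
    controllable class separability, a stratified cross-validation and
    MCC/AUC evaluation harness, tidy() and glance() accessors, ggplot2
    diagnostics, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mixOmics,
    nnet,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
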