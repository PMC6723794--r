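Package: dtibench
Title: Benchmarking Target Feature Families for Drug-Target Interaction
    Prediction from Transcriptome Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, fully synthetic benchmark of three families of
    protein-target features -- knockdown expression profiles, protein-protein
    interaction network embeddings (biased second-order random walks with
    skip-gram training), and pathway-membership embeddings (a GloVe-style
    weighted least-squares fit to pathway co-occurrence counts) -- for
    predicting drug-target interactions from drug-induced landmark expression
    profiles. Includes a latent-space synthetic-data generator with planted
    interactions, a two-block feedforward neural network trained with Adam,
    dropout and early stopping, naive Bayes, logistic-regression and
    random-forest baselines, positive-unlabeled negative sampling with
    leakage-free cross-validation/test partitions, and AUROC, AUPR,
    precision-at-top-k and class-ratio-robustness evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    fgsea,
    glmnet,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
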