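Package: nanoct
Title: Classifying Clinical-Trial Registry Summaries as Nanomedicine or Not
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A supervised text-mining pipeline for deciding whether a
    clinical-trial registry summary describes a nanotechnology-based
    intervention (a nanodrug or nanodevice) or a conventional one. Parses
    ClinicalTrials.gov study-record XML into a labeled corpus, proposes
    candidate records by dictionary/synonym matching, preprocesses text
    (tokenization, digit masking, stop-word and short-token removal, Porter
    stemming, unigram/bigram features), builds four bag-of-words document
    representations (binary, frequency, IDF, TF-IDF) with optional L2
    normalization, trains seven classifier families behind one contract
    (multinomial naive Bayes, decision tree, SGD/L1/L2 logistic regression,
    linear and degree-2 polynomial SVM), and evaluates them by stratified
    10-fold, leave-one-out and self-consistency validation with precision,
    recall, F, MCC, Cohen's kappa, ROC/AUC, per-fold SEM and learning
    curves. A synthetic corpus generator with controllable class
    separability makes the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    e1071,
    rpart,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
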