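Package: feba
Title: Feature-Enhanced Boosting with Adversarial Training for Short-Text
    Depression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A feature-enhanced boosting framework for binary classification
    of short social-media texts, aimed at depression-style signal detection.
    Provides a deterministic text-preprocessing pipeline (contraction
    expansion, emoji-to-text, curse-word retention, rule lemmatization),
    spectral word embeddings with mean-pooled or attention-pooled document
    vectors, scaled dot-product self-attention feature weighting,
    lexicon-based recursive sentiment-tree scoring on the 0-4 scale, decision
    tree importance driven recursive feature elimination producing optimized
    feature sets, a sequential boosting ensemble that additively re-weights
    misclassified samples with validation-gated weighted majority voting, a
    fast-gradient-sign-method (FGSM) adversarial layer with dual-loss defended
    training, and an evaluation harness (confusion metrics, ROC and
    precision-recall curves, portion learning curves, paired t-tests against a
    fixed baseline, permutation Shapley attribution). Ships seeded synthetic
    corpus and feature-matrix generators so the whole pipeline runs with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    rpart,
    optparse
Config/testthat/edition: 3
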