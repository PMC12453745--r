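# feba — feature-enhanced boosting with adversarial training for short-text screening

`feba` is an R toolkit for binary classification of short social-media
texts, built around the problem of screening posts for depression-style
language. It is aimed at computational researchers in digital mental health
and at anyone who needs a fully self-contained, deterministic reference
implementation of a feature-engineering + boosting + adversarial-training
pipeline: every stage runs from packaged resources and seeded generators,
with no downloads, pretrained weights or external services.

## What it implements

**Feature-engineering pipeline.** Raw posts are cleaned deterministically
(emoji → dictionary names, contraction expansion, URL/mention/hashtag
stripping, curse-word retention, rule lemmatization), embedded with
spectral word vectors (PPMI + truncated SVD, the deterministic counterpart
of skip-gram training; default d = 80), pooled per document (unweighted
mean, optionally concatenated with attention-pooled features from a scaled
dot-product self-attention layer, softmax(QKᵀ/√h)·V), augmented with a
recursive sentiment-tree score on the 0–4 scale, and reduced by recursive
feature elimination driven by a CART/Gini decision tree (`max_depth = 10`,
`min_samples_split = 5`, 10 iterations) to an **optimized feature set**.

**Classification pipeline.** Small neural weak learners (weighted logistic
regression and a one-hidden-layer MLP) are trained sequentially under the
per-sample weighted loss

    min_θ  Σᵢ wᵢ · L(Yᵢ, Ŷᵢ; θ),

with the additive re-weighting rule `wᵢ ← wᵢ + 1` for every training sample
the current learner misclassifies. A learner joins the ensemble only if its
validation accuracy exceeds a threshold (default 0.5); its vote weight is
that accuracy, and prediction is weighted majority voting with the winning
vote share as confidence.

**Adversarial layer.** FGSM perturbs document embeddings along the sign of
the input gradient, `x' = x + ε·sign(∇ₓJ(θ, x, y))` (ε = 0.05 by default);
defended training minimizes the dual loss `L = L_org + λ·L_adv` with fresh
FGSM examples each epoch. With ε = 0 the defended path reduces exactly to
undefended training.

**Evaluation.** Confusion metrics, threshold-swept ROC/PR curves with
trapezoidal AUC, portion learning curves (20/40/60/80%, repeated stratified
resampling), a paired t-test of metric blocks against a fixed 80% baseline,
and exact/sampled permutation-Shapley feature attribution. A comparison
harness pits five baseline families (SVM, kNN, random forest, naive Bayes,
logistic regression) against the same data as bag-of-words vs optimized
features.

**Synthetic data.** Seeded generators produce two-class short-text corpora
(class-informative vocabulary at a configurable log-odds effect size, with
synonym-substitution, sarcasm-marker and emoji noise) and labeled Gaussian
feature matrices with planted informative dimensions — the study
conditions for all tests. The time complexity of the boosting loop is
O(T·(n·d + E)) for T boosting iterations over n documents with d features
and per-learner training cost E; at the packaged scale a full run takes a
few seconds on one core.

## Worked example

```r
library(feba)

g   <- generate_corpus(corpus_spec(seed = 1))   # 2,000 labeled synthetic posts
res <- run_pipeline(g$docs, pipeline_config(seed = 1))

res$selection$optimized
#> <feba_ofs> 2000 documents x 20 selected features
res$ensemble
#> <feba_ensemble> 6/6 learners accepted (threshold 0.50)
#>   vote weights: 0.848, 0.860, 0.835, 0.840, 0.843, 0.843
res$metrics$test$accuracy
#> [1] 0.845
res$metrics$roc_auc
#> [1] 0.8764375
res$metrics$attack
#> <feba_attack_report> eps = 0.05: clean accuracy 0.845, attacked accuracy 0.275
```

Reading: from 146 engineered features (80 mean-pooled + 64 attention-pooled
+ 2 sentiment), RFE keeps 20; all six weak learners clear the validation
gate and vote with weights equal to their validation accuracies; the
ensemble classifies 84.5% of held-out documents correctly (ROC AUC 0.876),
but an FGSM attack at ε = 0.05 collapses it to 27.5% — the headroom the
defended variant (`pipeline_config(adversarial = TRUE)`) recovers, lifting
attacked accuracy to roughly 0.79 on the same data.

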