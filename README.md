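# nanoct

Supervised text classification of clinical-trial registry summaries:
does a registered study test a nanotechnology-based intervention (a
nanodrug or nanodevice, the *nano* class) or a conventional one
(*non-nano*)?

Public registries such as ClinicalTrials.gov do not record this
distinction, and even domain experts find it hard to tell from a summary
alone. `nanoct` implements the full pipeline for learning the
distinction from labeled summaries and applying it at scale:

- **Record I/O** — parse study-record XML into a labeled corpus
  (`parse_ct_record()`, `load_label_table()`, `assemble_corpus()`), with
  a JSON-lines interchange format between stages.
- **Dictionary retrieval** — match curated term/synonym lists (e.g.
  concepts exported from a biomedical metathesaurus) against a local
  corpus to propose candidate records for review (`match_terms()`,
  `propose_candidates()`), including the prefix matching public registry
  search lacks.
- **Preprocessing** — tokenization on punctuation/blanks, digit masking
  (`50 mg` → `## mg`), lowercasing, stop-word and short-token removal,
  Porter stemming, and unigram/bigram feature bags
  (`normalize_tokens()`, `document_features()`).
- **Vectorization** — sparse document-term matrices under four
  bag-of-words weightings with optional L2 row normalization
  (`weight_matrix()`): binary presence, term frequency tf(t, d),
  presence-weighted idf(t) = ln(N/df(t)), and tf-idf
  tf(t, d) · ln(N/df(t)). A feature occurring in every document gets
  idf exactly 0 and drops out.
- **Classification** — seven families behind one train/score/predict
  contract (`train_model()`): multinomial naive Bayes (works on
  fractional tf-idf values), a pruned decision tree, SGD logistic
  regression, L1- and L2-regularized logistic regression, and linear /
  degree-2 polynomial SVMs. L1 logistic regression with the IDF
  representation is the reference configuration: the L1 penalty performs
  implicit feature selection, yielding sparse, inspectable models.
- **Evaluation** — stratified 10-fold cross-validation (per-fold metrics
  with SEM), leave-one-out (pooled into a single confusion matrix), and
  self-consistency; weighted TPR/FPR, precision, recall, F, Matthews
  correlation, Cohen's kappa, rank-based ROC/AUC, and learning curves
  (`run_validation()`, `confusion_metrics()`, `roc_auc()`,
  `learning_curve()`). Vectorization is refit inside every training
  split, so no document frequencies leak from held-out text. For a
  balanced corpus, kappa = 2·accuracy − 1 exactly.
- **Synthetic corpora** — a generator (`generate_corpus()`) emulating a
  balanced two-class corpus with heavy-tailed document lengths
  (log-normal targeting mean 732 / sd 1001 tokens, floor 111) and
  sparse, token-level injection of class-specific terms, so the whole
  pipeline is testable without downloads.

## Worked example

```r
library(nanoct)

cfg <- generator_config(n_per_class = 100, injection_rate = 0.05, seed = 42)
corpus <- generate_corpus(cfg)
corpus
#> <labeled_corpus> 200 records (nano: 100, non-nano: 100)

bags <- corpus_features(corpus, n = 1)        # unigram bags per document
round(corpus_feature_stats(bags)$summary, 1)  # document-length profile
#>        min  max  mean    sd
#> total  111 6925 681.0 798.4
#> unique  56 1001 219.2 151.3

spec <- classifier_spec("l1_logreg", seed = 1)
report <- run_validation(bags, corpus$label, scheme = "idf", spec,
                         mode = "kfold", k = 10, seed = 1)
report
#> <evaluation_report> l1_logreg + idf, mode=kfold
#>   pooled: tpr=0.980 precision=0.980 f=0.980 mcc=0.960 kappa=0.960 auc=0.999
#>   k-fold SEM: tpr=0.0153 mcc=0.0273 auc=0.0000
```

The pooled weighted TP rate (= accuracy on this balanced corpus) is
0.980 with kappa 0.960 — the balanced-corpus identity kappa =
2·accuracy − 1 at work — and the per-fold SEM quantifies fold-to-fold
variability. The fitted L1 model is sparse and its heaviest weights name
the class-specific vocabulary planted by the generator:

```r
vocab <- build_vocabulary(bags)
model <- train_model(weight_matrix(bags, vocab, "idf"), corpus$label, spec)
head(sort(abs(model_weights(model)$weights), decreasing = TRUE), 5)
#>  ctrlsigaa  nanosigaa nanosigaaq ctrlsigaaj ctrlsigaaq
#>  1.0929280  0.9270406  0.9029101  0.6698199  0.6359022
```

On real registry data, replace the generator with
`read_ct_records()` + `load_label_table()` + `assemble_corpus()`.
A thin command-line wrapper over these functions ships in
`inst/cli/nanoct.R` (subcommands `corpus`, `synth`, `retrieve`,
`evaluate`, `train`, `predict`).

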