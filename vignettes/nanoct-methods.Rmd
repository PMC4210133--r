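---
title: "Methods: bag-of-words classification of clinical-trial summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bag-of-words classification of clinical-trial summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`nanoct` decides whether a clinical-trial registry summary describes a
nanotechnology-based intervention (*nano*) or a conventional one
(*non-nano*). The modelling assumption is deliberately simple:
nanomedicine vocabulary ("liposomal", "nanoparticle", "micelle",
"nanosuspension", ...) acts as a set of sparse lexical markers inside
otherwise ordinary clinical prose, usually as single composite words
modifying a biomedical referent rather than as multiword constructions.
A bag-of-words representation with a linear classifier is therefore well
matched to the signal: word order carries little of it, and the
discriminating terms are rare both within a document and across the
corpus.

Each document $d$ becomes a sparse vector over the corpus vocabulary.
Four weightings are provided for a term $t$ with within-document
frequency $\mathrm{tf}(t,d)$ and document frequency $\mathrm{df}(t)$ in
an $N$-document corpus:

| scheme      | entry                                                   |
|-------------|---------------------------------------------------------|
| binary      | $1[t \in d]$                                            |
| frequency   | $\mathrm{tf}(t,d)$                                      |
| idf         | $1[t \in d]\,\ln(N/\mathrm{df}(t))$                     |
| tfidf       | $\mathrm{tf}(t,d)\,\ln(N/\mathrm{df}(t))$               |

with optional scaling of each document vector to unit Euclidean norm.
Two conventions here were genuinely open and are package decisions:

- **The idf formula** is $\ln(N/\mathrm{df})$ with no smoothing and no
  additive constant, because the representation's purpose — terms
  occurring in every document are eliminated — requires
  $\mathrm{idf} = 0$ exactly at $\mathrm{df} = N$.
- **The "idf" scheme ignores term frequency** (presence × idf). This
  makes it genuinely distinct from both the binary scheme (which ignores
  global rarity) and tfidf (which keeps the local term count). Under
  this reading an idf-weighted document is a binary vector re-scaled
  feature-wise by global rarity, which is exactly the regime where
  sparse lexical markers are informative and verbose documents are not
  rewarded for repetition.

The reference configuration is L1-regularized logistic regression on
idf-weighted unigrams: the lasso penalty performs implicit feature
selection, so the fitted model is a short, inspectable list of signed
term weights.

## Preprocessing

The pipeline from raw text to features is fixed, and its order matters:

1. tokenize on anything that is not alphanumeric or underscore;
2. replace every digit by `#` (numbers contribute shape, not value);
3. lowercase;
4. remove stop words;
5. remove tokens shorter than 3 characters;
6. Porter-stem the survivors.

Consequences of the ordering, each covered by a test: `"100"` survives
as `"###"` because masking precedes the length filter, while `"50"`
(`"##"`) does not; stems shorter than three characters can exist because
the length filter applies to pre-stem tokens; stop-word comparison
happens after lowercasing.

The stop-word list is a frozen copy of a standard English list shipped
under `inst/extdata/`, so results cannot drift with external library
versions. The Porter stemmer is implemented in the package (R/porter.R)
from the original five-step rule set, with a frozen reference word list
in the tests; stemming is not idempotent in general (that is inherent to
the algorithm: "intervention" → "intervent" → "interv"), and the
idempotence property is asserted on a vocabulary of stems that are fixed
points.

Record fields are newline-joined when a study record is parsed, and the
newline is a hard boundary: bigrams never pair tokens across unrelated
fields. Bigram features join their two tokens with a single space, a
character that cannot occur inside a token. Which XML elements
constitute a record's "text" is configurable;
`default_text_fields()` lists the free-text elements of the public
study-record schema (titles, summaries, descriptions, conditions,
intervention names/types, keywords).

Dictionary retrieval (`match_terms()`) deliberately runs on the raw
surface token stream, *before* masking and stemming, because curated
term lists contain surface forms and emulate keyword searches against a
registry's own engine. Hyphens separate tokens, so "nab-paclitaxel"
matches the phrase "nab paclitaxel". In prefix mode the final token of a
term matches any token it prefixes; token matches are therefore always a
subset of prefix matches, a tested invariant.

## Classifiers

All seven families sit behind one contract — `train_model()`,
`score_model()`, `predict_model()` — with deterministic training given a
seed, and a documented tie rule: a score exactly at the decision
threshold (0.5 for probability scorers, 0 for SVM margins) goes to the
positive class.

The module owns the contract and the hyperparameter surface, not the
solver internals; established optimization backends are used where they
exist:

- `l1_logreg` / `l2_logreg`: coordinate-descent GLM fits (glmnet) at a
  fixed, mild penalty (default $\lambda = 0.01$); no tuning loop is
  implemented, because none is part of the method.
- `svm_linear` / `svm_poly2`: libsvm via e1071, kernels $u'v$ and
  $(u'v)^2$, cost 1, no internal rescaling.
- `c45`: a pruned axis-aligned decision tree via rpart. This is a
  CART-family tree (impurity splits with complexity pruning) rather than
  a gain-ratio tree; at the contract level — interpretable conjunctions
  of features, leaf-proportion scores — the behaviour is equivalent, and
  tree performance is never the pipeline's selling point.
- `mnb`: hand-written multinomial naive Bayes with additive smoothing
  $\alpha$ (default 1). It accepts real-valued features, so tf-idf
  inputs are valid; smoothed class-conditional log-probabilities are
  linear in the features either way.
- `sgd_logreg`: hand-written stochastic gradient descent on the
  logistic loss with a small L2 term, a decaying step size
  $\eta_t = \eta_0/(1 + \eta_0 \lambda t)$ and a fixed epoch count;
  shuffling is seeded, making it the one family whose determinism
  depends on the spec seed.

## Validation and metrics

Three modes: stratified k-fold (default $k=10$), leave-one-out, and
self-consistency (train = test, an optimistic stability reference).
Inside *every* training split the vocabulary, document frequencies and
idf are recomputed from the training documents alone; a feature seen
only in held-out text has no column at all. A property test plants a
private marker token in each document and asserts it never reaches a
training vocabulary it should not.

Fold assignment deals shuffled within-class indices round-robin, so
per-fold class proportions match the corpus to within one document; a
balanced 1000-document corpus yields ten folds of exactly 100 at 50/50.

Metrics are computed from the pooled confusion matrix (and per fold for
k-fold, whose spread is reported as SEM = sd/√k). Reporting uses
support-weighted averaging of the per-class one-vs-rest values — the
convention that makes a single TPR per model equal overall accuracy on a
balanced corpus. That convention gives the exact identity
$\kappa = 2\,\mathrm{accuracy} - 1$ for balanced true classes: expected
agreement is $\tfrac12$ regardless of the prediction marginals, since
$p_e = (500\,m_1 + 500\,m_2)/1000^2$ with $m_1 + m_2 = 1000$. The
acceptance suite uses this identity to tie kappa values to their
corresponding accuracy figures exactly. Degenerate cases are pinned
down: MCC is 0 when any marginal factor vanishes, kappa is 0 when
$p_e = 1$, and 0/0 rates are reported as 0.

AUC is rank-based (midranks for ties — equivalent to concordant-pair
counting with half credit), with ROC points emitted at every distinct
threshold. Leave-one-out predictions are pooled into one confusion
matrix before computing metrics, because per-instance rates are
undefined; consequently LOO reports no SEM.

The learning curve draws a *fresh* stratified split per fraction
(default grid 0.10–0.90 by 0.10, then 0.95), trains on the fraction and
scores the complement; the run seed is recorded on the result.

## The synthetic generator: what it emulates and what it does not

`generate_corpus()` produces a balanced two-class corpus in which

- per-document token counts follow a log-normal matched by moments to a
  target mean 732 / sd 1001 with a floor of 111 tokens — the
  heavy-tailed document-length profile of real registry summaries;
- background tokens are drawn from a Zipf law (default exponent 1.1 over
  2000 types), giving a realistic skew of document frequencies — most
  features rare, a few ubiquitous (at these defaults a unigram occurs in
  roughly 2% of documents on average, matching the sparsity of real
  summary vocabulary);
- class identity enters only through token-level injection: each emitted
  token is, with probability `injection_rate`, one of the class's own
  discriminative terms (default 20 per class), with probability
  `cross_rate` one of the other class's, and a background draw
  otherwise. Token-level (not document-level) injection keeps the
  markers sparse within documents, mirroring how nanomedicine terms
  behave in real summaries.

Setting `injection_rate == cross_rate` makes the class-conditional
distributions identical — a null corpus on which any classifier's AUC
should be ≈ 0.5; that bound is asserted in the acceptance suite.
Generated tokens are lowercase alphabetic, length ≥ 3 and disjoint from
the stop-word list, so preprocessing is a near-no-op on them and
pipeline behaviour is attributable to the weighting and the classifier.

What the generator does **not** emulate: natural-language syntax or any
bigram dependence (tokens are exchangeable within a document), topical
correlation between background words, label noise, and the
multi-synonym surface variation real nanomedicine terms show. Passing
the synthetic acceptance checks therefore demonstrates that the
pipeline's machinery is correct and that it recovers sparse lexical
signal at realistic document shapes — not that any particular accuracy
will be attained on live registry data, whose absolute performance
depends on the curated corpus itself.

## Problem sizes and numerical choices

The test and acceptance runs use 100 documents per class (200 total) for
leave-one-out experiments and the learning curve, and the full default
500 per class for the study-scale 10-fold benchmark in
`scripts/acceptance.R` — sizes at which every check completes in minutes
on one CPU while leaving the asserted effects far from their thresholds
(signal-corpus LOO AUC ≈ 0.9996 against a bound of 0.90).

The learning-curve check uses a deliberately weak signal
(`injection_rate = 0.005`): at the default 0.05 the task saturates
(≈ 0.99 accuracy from a 10% training fraction already), leaving no
rising regime for a rank correlation to detect. The weak-signal corpus
is the regime where training-set size visibly matters, which is what a
learning curve is for.

Other numerical conventions, stated once: brute-force oracle agreement
is asserted at 1e-12 (metrics, AUC) and 1e-9 (idf/tfidf weighting);
row normalization treats an all-zero document as zero rather than NaN;
glmnet is given a short descending λ-path ending at the requested λ
(fits at a single point are less stable); and when a training matrix has
a single column, a zero column is padded internally to satisfy the
solver, never affecting scores.

## Known limitations

- The decision-tree family is CART-style, not a gain-ratio tree;
  results for that family are not expected to be bit-compatible with
  other toolkits' C4.5 implementations (nor are the SVM/GLM solvers,
  which differ across workbenches in tolerance and internal scaling).
- Multiword prefix matching applies the prefix only to the final token
  of a term.
- The "idf" scheme's presence-times-idf reading is one of two defensible
  conventions (the other retains tf); it is isolated in one function and
  trivial to swap.
- Real registry corpora drift: absolute metric values reported for any
  fixed snapshot are not reproducible from the live database, which is
  why the automated checks rest on synthetic corpora and exact metric
  identities instead.
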