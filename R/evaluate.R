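#' Stratified k-fold assignment
#'
#' Partitions documents into `k` disjoint test folds so that each fold's
#' class proportions match the global proportions to within one document.
#' Within each class, shuffled indices are dealt round-robin across folds,
#' so a balanced corpus of 1000 (500/500) at k = 10 yields ten folds of
#' exactly 100 with 50/50.
#'
#' @param labels character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed; identical seeds give identical folds.
#' @return list of `k` sorted integer vectors of test indices, jointly
#'   partitioning `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (k > min(counts)) {
    stop("k = ", k, " exceeds the smallest class count (", min(counts), ")")
  }
  folds <- vector("list", k)
  .with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Confusion counts for binary predictions
#'
#' @param truth,predicted character vectors of true and predicted labels.
#' @param positive the positive class.
#' @return a `confusion_matrix`: list with integer counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive = "nano") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  structure(
    list(tp = sum(truth == positive & predicted == positive),
         fp = sum(truth != positive & predicted == positive),
         tn = sum(truth != positive & predicted != positive),
         fn = sum(truth == positive & predicted != positive),
         positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> tp=", x$tp, " fp=", x$fp, " tn=", x$tn,
      " fn=", x$fn, " (positive: ", x$positive, ")\n", sep = "")
  invisible(x)
}

# 0/0 rates are reported as 0 (no predicted/true members of the class)
.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Metrics from a confusion matrix
#'
#' Computes true/false positive rate, precision, recall, F-measure, Matthews
#' correlation coefficient and Cohen's kappa. Per-class values are combined
#' by support-weighted averaging when `averaging = "weighted"` (the
#' convention behind single-number-per-model workbench reports; on a balanced
#' corpus the weighted TPR equals overall accuracy, so kappa = 2*accuracy - 1
#' exactly). MCC is 0 when any marginal factor is 0; kappa is 0 when expected
#' agreement is 1. Degenerate 0/0 rates are reported as 0.
#'
#' @param cm a [confusion_counts()] result.
#' @param averaging `"weighted"` (default) or `"per-class"`.
#' @return a `metric_set`: list with `tpr`, `fpr`, `precision`, `recall`,
#'   `f_measure`, `mcc`, `kappa`, `accuracy`, the `averaging` used and a
#'   `per_class` data frame.
#' @export
confusion_metrics <- function(cm, averaging = c("weighted", "per-class")) {
  averaging <- match.arg(averaging)
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix")

  # per-class one-vs-rest rates; class 1 = positive, class 2 = negative
  prec <- c(.safe_div(tp, tp + fp), .safe_div(tn, tn + fn))
  rec <- c(.safe_div(tp, tp + fn), .safe_div(tn, tn + fp))
  fpr <- c(.safe_div(fp, fp + tn), .safe_div(fn, fn + tp))
  f <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- c(tp + fn, tn + fp)

  per_class <- data.frame(class = c(cm$positive, "other"),
                          precision = prec, recall = rec, tpr = rec,
                          fpr = fpr, f_measure = f, support = support)

  wavg <- function(v) sum(v * support) / n
  if (averaging == "weighted") {
    precision <- wavg(prec); recall <- wavg(rec)
    tpr <- recall; fprm <- wavg(fpr); f_measure <- wavg(f)
  } else {
    precision <- prec[1]; recall <- rec[1]
    tpr <- rec[1]; fprm <- fpr[1]; f_measure <- f[1]
  }

  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else
    (tp * tn - fp * fn) / sqrt(tp + fp) / sqrt(tp + fn) /
    sqrt(tn + fp) / sqrt(tn + fn)

  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)

  structure(
    list(tpr = tpr, fpr = fprm, precision = precision, recall = recall,
         f_measure = f_measure, mcc = mcc, kappa = kappa, accuracy = po,
         averaging = averaging, per_class = per_class),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set %s> tpr=%.3f fpr=%.3f precision=%.3f recall=%.3f f=%.3f mcc=%.3f kappa=%.3f\n",
    x$averaging, x$tpr, x$fpr, x$precision, x$recall, x$f_measure, x$mcc,
    x$kappa))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' AUC is computed from midranks (equivalent to counting concordant score
#' pairs with ties worth 1/2), and ROC points are emitted at every distinct
#' score threshold.
#'
#' @param scores numeric positive-class scores.
#' @param labels parallel class labels; both classes must be present.
#' @param positive the positive class.
#' @return list with `auc` and `points` (data frame `threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(scores, labels, positive = "nano") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an ROC curve")
  }
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, numeric(1))
  list(auc = auc,
       points = data.frame(threshold = c(Inf, thr),
                           tpr = c(0, tpr), fpr = c(0, fpr)))
}

# fit on a training index set, score/predict on a test set; the vocabulary,
# document frequencies and idf come from the training split only
.fit_split <- function(bags, labels, train_idx, test_idx, scheme, spec,
                       normalize, positive) {
  vocab <- build_vocabulary(bags[train_idx])
  xtr <- weight_matrix(bags[train_idx], vocab, scheme, normalize)
  xte <- weight_matrix(bags[test_idx], vocab, scheme, normalize)
  model <- train_model(xtr, labels[train_idx], spec, positive = positive)
  scores <- score_model(model, xte)
  list(scores = scores,
       predicted = predict_model(model, xte),
       truth = labels[test_idx])
}

#' Run a validation experiment
#'
#' Trains and evaluates one scheme/classifier configuration under stratified
#' k-fold cross-validation, leave-one-out (LOO), or self-consistency
#' (train = test = full corpus). Vectorization is refit inside every training
#' split: vocabulary, document frequencies and idf are computed from the
#' training documents only, so no information leaks from held-out text.
#'
#' k-fold reports per-fold metrics, their mean, and the standard error of the
#' mean (sample sd across folds / sqrt(k)); LOO pools all n held-out
#' predictions into a single confusion matrix (per-instance rates are
#' undefined, so no SEM is reported).
#'
#' @param bags list of feature bags (from [corpus_features()]).
#' @param labels parallel class labels.
#' @param scheme weighting scheme, see [weight_matrix()].
#' @param spec a [classifier_spec()].
#' @param mode `"kfold"`, `"loo"` or `"self_consistency"`.
#' @param k number of folds for `"kfold"`.
#' @param seed integer seed for fold assignment.
#' @param normalize L2-normalize document vectors.
#' @param positive the positive class.
#' @return an `evaluation_report`: list with `mode`, `scheme`, `family`,
#'   `seed`, `pooled` metrics (a [confusion_metrics()] metric set plus
#'   `auc`), pooled `confusion`, `scores`, and for k-fold `fold_metrics`
#'   (data frame), `sem` (named vector) and `folds` (the assignment).
#' @export
run_validation <- function(bags, labels, scheme, spec,
                           mode = c("kfold", "loo", "self_consistency"),
                           k = 10L, seed = 1L, normalize = FALSE,
                           positive = "nano") {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  stopifnot(length(bags) == length(labels))
  n <- length(bags)

  splits <- switch(
    mode,
    kfold = stratified_kfold(labels, k = k, seed = seed),
    loo = as.list(seq_len(n)),
    self_consistency = list(seq_len(n))
  )

  fold_rows <- NULL
  all_scores <- numeric(0)
  all_truth <- character(0)
  all_pred <- character(0)
  for (f in seq_along(splits)) {
    test_idx <- splits[[f]]
    train_idx <- if (mode == "self_consistency") test_idx
                 else setdiff(seq_len(n), test_idx)
    res <- .fit_split(bags, labels, train_idx, test_idx, scheme, spec,
                      normalize, positive)
    all_scores <- c(all_scores, res$scores)
    all_truth <- c(all_truth, res$truth)
    all_pred <- c(all_pred, res$predicted)
    if (mode == "kfold") {
      cm <- confusion_counts(res$truth, res$predicted, positive)
      ms <- confusion_metrics(cm)
      auc_f <- roc_auc(res$scores, res$truth, positive)$auc
      fold_rows <- rbind(fold_rows, data.frame(
        fold = f, tpr = ms$tpr, fpr = ms$fpr, precision = ms$precision,
        recall = ms$recall, f_measure = ms$f_measure, mcc = ms$mcc,
        kappa = ms$kappa, auc = auc_f, accuracy = ms$accuracy))
    }
  }

  pooled_cm <- confusion_counts(all_truth, all_pred, positive)
  pooled <- confusion_metrics(pooled_cm)
  pooled$auc <- roc_auc(all_scores, all_truth, positive)$auc

  sem <- NULL
  if (mode == "kfold") {
    metric_cols <- setdiff(names(fold_rows), "fold")
    sem <- vapply(fold_rows[metric_cols],
                  function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
  }

  structure(
    list(mode = mode, scheme = scheme, family = spec$family,
         normalized = normalize, seed = seed, k = if (mode == "kfold") k else NA,
         pooled = pooled, confusion = pooled_cm,
         fold_metrics = fold_rows, sem = sem,
         folds = if (mode == "kfold") splits else NULL,
         scores = all_scores, truth = all_truth, predicted = all_pred),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$family, " + ", x$scheme,
      if (x$normalized) " (normalized)" else "", ", mode=", x$mode, "\n",
      sep = "")
  cat(sprintf("  pooled: tpr=%.3f precision=%.3f f=%.3f mcc=%.3f kappa=%.3f auc=%.3f\n",
              x$pooled$tpr, x$pooled$precision, x$pooled$f_measure,
              x$pooled$mcc, x$pooled$kappa, x$pooled$auc))
  if (!is.null(x$sem)) {
    cat(sprintf("  k-fold SEM: tpr=%.4f mcc=%.4f auc=%.4f\n",
                x$sem["tpr"], x$sem["mcc"], x$sem["auc"]))
  }
  invisible(x)
}

#' Flatten an evaluation report to one table row
#'
#' @param report an [run_validation()] result.
#' @return one-row data frame with identifiers, pooled metrics and SEM
#'   columns (SEM is `NA` outside k-fold), mirroring a results-table layout.
#' @export
report_row <- function(report) {
  p <- report$pooled
  row <- data.frame(
    family = report$family, scheme = report$scheme,
    normalized = report$normalized, mode = report$mode,
    tpr = p$tpr, fpr = p$fpr, precision = p$precision, recall = p$recall,
    f_measure = p$f_measure, mcc = p$mcc, kappa = p$kappa, auc = p$auc)
  for (m in c("tpr", "mcc", "auc")) {
    row[[paste0("sem_", m)]] <- if (is.null(report$sem)) NA_real_
                                else unname(report$sem[m])
  }
  row
}

#' Learning curve: accuracy vs training fraction
#'
#' For each fraction, draws a fresh stratified split with `fraction` of each
#' class as the training set (the complement is the test set), refits
#' vectorization and the classifier on the training side, and records test
#' accuracy. Default fractions 0.10, 0.20, ..., 0.90, 0.95.
#'
#' @inheritParams run_validation
#' @param fractions strictly increasing training fractions in (0, 1).
#' @return data frame with `fraction`, `n_train`, `n_test`, `accuracy`;
#'   attribute `seed` records the run seed.
#' @export
learning_curve <- function(bags, labels, scheme, spec,
                           fractions = c(seq(0.1, 0.9, by = 0.1), 0.95),
                           seed = 1L, normalize = FALSE, positive = "nano") {
  if (any(fractions <= 0) || any(fractions >= 1) ||
      any(diff(fractions) <= 0)) {
    stop("fractions must be strictly increasing within (0, 1)")
  }
  labels <- as.character(labels)
  n <- length(bags)
  classes <- sort(unique(labels))
  out <- NULL
  for (i in seq_along(fractions)) {
    frac <- fractions[i]
    train_idx <- integer(0)
    .with_seed(seed + i, {
      for (cl in classes) {
        idx <- which(labels == cl)
        n_tr <- round(frac * length(idx))
        if (n_tr < 1 || n_tr >= length(idx)) {
          stop("fraction ", frac, " leaves < 1 document per class in train ",
               "or test")
        }
        train_idx <- c(train_idx, sample(idx, n_tr))
      }
    })
    test_idx <- setdiff(seq_len(n), train_idx)
    res <- .fit_split(bags, labels, train_idx, test_idx, scheme, spec,
                      normalize, positive)
    out <- rbind(out, data.frame(
      fraction = frac, n_train = length(train_idx),
      n_test = length(test_idx),
      accuracy = mean(res$predicted == res$truth)))
  }
  attr(out, "seed") <- seed
  out
}
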