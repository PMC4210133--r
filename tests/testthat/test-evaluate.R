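test_that("stratified folds are balanced, disjoint and reproducible", {
  labels <- rep(c("nano", "non-nano"), each = 500)
  folds <- stratified_kfold(labels, k = 10, seed = 42)
  expect_length(folds, 10)
  expect_true(all(vapply(folds, length, integer(1)) == 100))
  for (f in folds) {
    expect_equal(sum(labels[f] == "nano"), 50)
  }
  expect_equal(sort(unlist(folds)), 1:1000)  # partition

  expect_identical(stratified_kfold(labels, k = 10, seed = 42), folds)
  other <- stratified_kfold(labels, k = 10, seed = 43)
  expect_false(identical(other, folds))
  expect_equal(vapply(other, length, integer(1)),
               vapply(folds, length, integer(1)))
})

test_that("small stratified folds keep one document per class", {
  labels <- rep(c("nano", "non-nano"), 5)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  expect_true(all(vapply(folds, length, integer(1)) == 2))
  for (f in folds) expect_equal(sum(labels[f] == "nano"), 1)
  expect_error(stratified_kfold(labels, k = 6), "class count")
})

test_that("confusion metrics reproduce the balanced worked example", {
  cm <- structure(list(tp = 478, fp = 23, tn = 477, fn = 22,
                       positive = "nano"), class = "confusion_matrix")
  ms <- confusion_metrics(cm)
  expect_equal(ms$tpr, 0.955)
  expect_equal(ms$accuracy, 0.955)
  expect_equal(ms$kappa, 0.910, tolerance = 1e-12)
  expect_equal(ms$mcc, 0.9100, tolerance = 1e-4)
  expect_equal(ms$fpr, 0.045)
})

test_that("perfect and degenerate confusion matrices behave as defined", {
  perfect <- confusion_counts(c("nano", "non-nano"), c("nano", "non-nano"))
  mp <- confusion_metrics(perfect)
  expect_equal(c(mp$precision, mp$recall, mp$f_measure, mp$mcc, mp$kappa),
               rep(1, 5))

  all_nano <- confusion_counts(rep(c("nano", "non-nano"), each = 10),
                               rep("nano", 20))
  ma <- confusion_metrics(all_nano)
  expect_equal(ma$kappa, 0)
  expect_equal(ma$mcc, 0)

  expect_error(confusion_metrics(structure(
    list(tp = 0, fp = 0, tn = 0, fn = 0, positive = "nano"),
    class = "confusion_matrix")), "empty")
})

test_that("kappa equals 2*accuracy - 1 exactly for balanced true classes", {
  set.seed(88)
  for (i in 1:200) {
    half <- sample(5:500, 1)
    tp <- sample(0:half, 1); fn <- half - tp
    tn <- sample(0:half, 1); fp <- half - tn
    cm <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                         positive = "nano"), class = "confusion_matrix")
    ms <- confusion_metrics(cm)
    expect_equal(ms$kappa, 2 * ms$accuracy - 1, tolerance = 1e-12)
  }
})

test_that("metrics agree with an independent naive reimplementation", {
  set.seed(99)
  for (i in 1:300) {
    counts <- as.list(sample(0:60, 4, replace = TRUE))
    names(counts) <- c("tp", "fp", "tn", "fn")
    if (Reduce(`+`, counts) == 0) counts$tp <- 1
    cm <- structure(c(counts, positive = "nano"), class = "confusion_matrix")
    got <- confusion_metrics(cm)
    want <- naive_metrics(counts$tp, counts$fp, counts$tn, counts$fn)
    for (m in names(want)) {
      expect_equal(got[[m]], want[[m]], tolerance = 1e-12, label = m)
    }
  }
})

test_that("rank-based AUC matches definitional cases and pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("nano", "nano", "non-nano", "non-nano"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6),
                       rep(c("nano", "non-nano"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("nano", "nano", "non-nano", "non-nano"))$auc, 0.75)

  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:200, 1)
    labels <- sample(c("nano", "non-nano"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("nano", "non-nano")
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.2), c("nano", "nano")), "both classes")
})

test_that("AUC agrees with pROC on a tied, unbalanced score set", {
  skip_if_not_installed("pROC")
  set.seed(7)
  labels <- sample(c("nano", "non-nano"), 80, replace = TRUE, prob = c(.3, .7))
  scores <- round(rnorm(80, ifelse(labels == "nano", .6, .4), .3), 1)
  got <- roc_auc(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("non-nano", "nano"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ROC points trace monotone cumulative rates", {
  set.seed(13)
  scores <- runif(40)
  labels <- rep(c("nano", "non-nano"), 20)
  pts <- roc_auc(scores, labels)$points
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("self-consistency on a separable toy reaches accuracy 1", {
  toy <- separable_toy()
  rep <- run_validation(toy$bags, toy$labels, "frequency",
                        classifier_spec("l1_logreg"),
                        mode = "self_consistency")
  expect_equal(rep$pooled$accuracy, 1)
  expect_equal(rep$pooled$kappa, 1)
})

test_that("leave-one-out pools exactly one prediction per document", {
  toy <- separable_toy()
  rep <- run_validation(toy$bags, toy$labels, "frequency",
                        classifier_spec("l1_logreg"), mode = "loo")
  n <- length(toy$bags)
  cm <- rep$confusion
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
  expect_length(rep$scores, n)
  expect_null(rep$sem)
})

test_that("k-fold pooled accuracy sits within 3 SEM of the fold mean", {
  cfg <- generator_config(n_per_class = 30, injection_rate = 0.03, seed = 71)
  corp <- generate_corpus(cfg)
  bags <- corpus_features(corp)
  rep <- run_validation(bags, corp$label, "idf", classifier_spec("l1_logreg"),
                        mode = "kfold", k = 5, seed = 12)
  expect_equal(nrow(rep$fold_metrics), 5)
  fold_mean <- mean(rep$fold_metrics$accuracy)
  sem <- stats::sd(rep$fold_metrics$accuracy) / sqrt(5)
  expect_lt(abs(rep$pooled$accuracy - fold_mean), max(3 * sem, 1e-9))
  expect_equal(unname(rep$sem["accuracy"]), sem)
})

test_that("no feature leaks from a fold's test documents into its training vocabulary", {
  bags <- random_bags(20, 10, seed = 5)
  # give every document a private marker feature
  for (i in seq_along(bags)) {
    bags[[i]] <- c(bags[[i]], stats::setNames(1L, paste0("private", i)))
  }
  labels <- rep(c("nano", "non-nano"), 10)
  folds <- stratified_kfold(labels, k = 4, seed = 2)
  for (f in folds) {
    vocab <- build_vocabulary(bags[-f])
    test_only <- paste0("private", f)
    expect_length(intersect(test_only, vocab$features), 0)
    xte <- weight_matrix(bags[f], vocab, "tfidf")
    expect_length(intersect(test_only, colnames(xte$matrix)), 0)
  }
})

test_that("learning curve uses the documented fraction grid and stratified splits", {
  frac <- c(seq(0.1, 0.9, by = 0.1), 0.95)
  expect_equal(frac[1], 0.10)
  expect_equal(frac[length(frac)], 0.95)

  cfg <- generator_config(n_per_class = 20, injection_rate = 0.1, seed = 81)
  corp <- generate_corpus(cfg)
  bags <- corpus_features(corp)
  lc <- learning_curve(bags, corp$label, "idf", classifier_spec("l1_logreg"),
                       fractions = c(0.5, 0.8), seed = 4)
  expect_equal(lc$fraction, c(0.5, 0.8))
  expect_equal(lc$n_train[1], 20)  # balanced half split
  expect_error(
    learning_curve(bags, corp$label, "idf", classifier_spec("l1_logreg"),
                   fractions = 0.01, seed = 4),
    "leaves < 1")
  expect_error(
    learning_curve(bags, corp$label, "idf", classifier_spec("l1_logreg"),
                   fractions = c(0.5, 0.4)),
    "strictly increasing")
})

test_that("report rows flatten pooled metrics with SEM only for k-fold", {
  toy <- separable_toy()
  r1 <- run_validation(toy$bags, toy$labels, "binary",
                       classifier_spec("mnb"), mode = "kfold", k = 2,
                       seed = 3)
  row <- report_row(r1)
  expect_equal(row$mode, "kfold")
  expect_false(is.na(row$sem_tpr))
  r2 <- run_validation(toy$bags, toy$labels, "binary",
                       classifier_spec("mnb"), mode = "loo")
  expect_true(is.na(report_row(r2)$sem_tpr))
})
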