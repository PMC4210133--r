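# Independent brute-force oracles and fixture builders. These deliberately
# recompute everything with naive dense loops, sharing no code with the
# package internals they check.

# dense document-term weights computed feature by feature
brute_force_weights <- function(bags, features, df, n_docs, scheme,
                                normalize = FALSE) {
  out <- matrix(0, nrow = length(bags), ncol = length(features),
                dimnames = list(names(bags), features))
  for (d in seq_along(bags)) {
    for (j in seq_along(features)) {
      t <- features[j]
      tf <- if (t %in% names(bags[[d]])) as.numeric(bags[[d]][[t]]) else 0
      if (tf == 0) next
      out[d, j] <- switch(scheme,
                          binary = 1,
                          frequency = tf,
                          idf = log(n_docs / df[[t]]),
                          tfidf = tf * log(n_docs / df[[t]]))
    }
  }
  if (normalize) {
    for (d in seq_len(nrow(out))) {
      nrm <- sqrt(sum(out[d, ]^2))
      if (nrm > 0) out[d, ] <- out[d, ] / nrm
    }
  }
  out
}

# document frequency by scanning every document for every feature
brute_force_df <- function(bags) {
  features <- sort(unique(unlist(lapply(bags, names))))
  vapply(features, function(t) {
    sum(vapply(bags, function(b) t %in% names(b), logical(1)))
  }, integer(1))
}

# confusion-matrix metrics written out naively, one formula per line
naive_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) 0 else a / b
  prec_pos <- div(tp, tp + fp); prec_neg <- div(tn, tn + fn)
  rec_pos <- div(tp, tp + fn); rec_neg <- div(tn, tn + fp)
  f_pos <- div(2 * prec_pos * rec_pos, prec_pos + rec_pos)
  f_neg <- div(2 * prec_neg * rec_neg, prec_neg + rec_neg)
  fpr_pos <- div(fp, fp + tn); fpr_neg <- div(fn, fn + tp)
  w_pos <- (tp + fn) / n; w_neg <- (tn + fp) / n
  acc <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  prod4 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (prod4 == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(prod4)
  list(tpr = w_pos * rec_pos + w_neg * rec_neg,
       fpr = w_pos * fpr_pos + w_neg * fpr_neg,
       precision = w_pos * prec_pos + w_neg * prec_neg,
       recall = w_pos * rec_pos + w_neg * rec_neg,
       f_measure = w_pos * f_pos + w_neg * f_neg,
       mcc = mcc, kappa = kappa, accuracy = acc)
}

# AUC by explicit concordant-pair counting with half credit for ties
brute_force_auc <- function(scores, labels, positive = "nano") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# random feature bags over a small alphabet
random_bags <- function(n_docs, n_features, seed) {
  set.seed(seed)
  alphabet <- paste0("feat", sprintf("%03d", seq_len(n_features)))
  bags <- lapply(seq_len(n_docs), function(d) {
    k <- sample.int(n_features, 1)
    feats <- sample(alphabet, k)
    stats::setNames(sample.int(5, k, replace = TRUE), feats)[order(feats)]
  })
  names(bags) <- sprintf("NCT%08d", seq_len(n_docs))
  bags
}

# a ClinicalTrials.gov-style study record as an XML string
make_ct_xml <- function(nct_id = "NCT00000001", brief_title = NULL,
                        official_title = NULL, brief_summary = NULL,
                        detailed_description = NULL, condition = NULL,
                        keyword = NULL) {
  block <- function(tag, content, textblock = FALSE) {
    if (is.null(content)) return("")
    inner <- if (textblock) {
      paste0("\n    <textblock>\n      ", content, "\n    </textblock>\n  ")
    } else content
    paste0("  <", tag, ">", inner, "</", tag, ">\n")
  }
  paste0(
    "<clinical_study>\n",
    "  <id_info><org_study_id>X-1</org_study_id><nct_id>", nct_id,
    "</nct_id></id_info>\n",
    block("brief_title", brief_title),
    block("official_title", official_title),
    block("brief_summary", brief_summary, textblock = TRUE),
    block("detailed_description", detailed_description, textblock = TRUE),
    block("condition", condition),
    block("keyword", keyword),
    "</clinical_study>"
  )
}

# a linearly separable toy: one class-defining feature plus shared noise
separable_toy <- function() {
  bags <- list(
    a1 = c(sig = 2L, common = 1L), a2 = c(sig = 1L, common = 2L),
    a3 = c(sig = 3L, common = 1L), a4 = c(sig = 1L, other = 1L, common = 1L),
    b1 = c(common = 2L, other = 1L), b2 = c(common = 1L),
    b3 = c(other = 2L, common = 1L), b4 = c(other = 1L, common = 3L)
  )
  list(bags = bags,
       labels = rep(c("nano", "non-nano"), each = 4L))
}
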