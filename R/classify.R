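#' Classifier families available behind the common contract
#'
#' @return character vector of family names.
#' @export
classifier_families <- function() {
  c("mnb", "c45", "sgd_logreg", "l1_logreg", "l2_logreg",
    "svm_linear", "svm_poly2")
}

#' Specify a classifier
#'
#' One specification object covers all seven families; only the
#' hyperparameters relevant to `family` are used. Defaults are mild,
#' untuned settings:
#' \describe{
#'   \item{lambda}{regularization strength for `l1_logreg`/`l2_logreg`
#'     (default 0.01, a mild penalty on unit-scale text features).}
#'   \item{cost}{soft-margin cost C for the SVM families (default 1).}
#'   \item{alpha}{additive smoothing for multinomial naive Bayes (default 1,
#'     Laplace).}
#'   \item{epochs, learning_rate, sgd_lambda}{SGD logistic regression: fixed
#'     epoch count (default 20), initial step size (default 0.5) with a
#'     decaying schedule, and a small L2 term (default 1e-4).}
#'   \item{tree_cp, tree_minsplit}{complexity-pruning and minimum-split
#'     controls for the decision tree (defaults 0.01 and 5).}
#' }
#' The polynomial SVM degree is fixed at 2.
#'
#' @param family one of [classifier_families()].
#' @param lambda,cost,alpha,epochs,learning_rate,sgd_lambda,tree_cp,tree_minsplit
#'   family-specific hyperparameters, see Details.
#' @param seed integer seed making training deterministic.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family, lambda = 0.01, cost = 1, alpha = 1,
                            epochs = 20L, learning_rate = 0.5,
                            sgd_lambda = 1e-4, tree_cp = 0.01,
                            tree_minsplit = 5L, seed = 1L) {
  family <- match.arg(family, classifier_families())
  if (lambda <= 0 || cost <= 0 || alpha <= 0) {
    stop("lambda, cost and alpha must be positive")
  }
  structure(
    list(family = family, lambda = lambda, cost = cost, alpha = alpha,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         sgd_lambda = sgd_lambda, tree_cp = tree_cp,
         tree_minsplit = as.integer(tree_minsplit),
         degree = if (family == "svm_poly2") 2L else NA_integer_,
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", x$family, "(seed", paste0(x$seed, ")\n"))
  invisible(x)
}

# coerce any accepted input to a dgCMatrix with feature names
.as_feature_matrix <- function(x) {
  if (inherits(x, "doc_term_matrix")) return(x$matrix)
  if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# run code with an isolated RNG stream seeded from `seed`
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Train a classifier
#'
#' Fits the family named in `spec` on a document-term matrix. Training is
#' deterministic given `(x, labels, spec$seed)`. The logistic families
#' minimize the regularized negative log-likelihood (L1 penalty for lasso,
#' squared L2 for ridge, small L2 for plain SGD); the SVM families maximize a
#' soft margin with a linear or degree-2 polynomial kernel; multinomial naive
#' Bayes fits class-conditional multinomials with additive smoothing over
#' possibly fractional feature values (so it also runs on TF-IDF input); the
#' decision tree grows axis-aligned splits with complexity pruning.
#'
#' @param x a [weight_matrix()] result, a matrix, or a `Matrix` sparse matrix
#'   (documents in rows).
#' @param labels character vector of class labels, both classes present.
#' @param spec a [classifier_spec()].
#' @param positive the positive class (defaults to `"nano"` when present,
#'   otherwise the lexicographically first label).
#' @return a `trained_model` exposing per-document scores via [score_model()]
#'   and hard labels via [predict_model()]; linear families expose
#'   coefficients via [model_weights()].
#' @export
train_model <- function(x, labels, spec, positive = NULL) {
  X <- .as_feature_matrix(x)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match matrix rows")
  if (nrow(X) < 2L) stop("need at least 2 training documents")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("training labels must contain exactly two classes, got: ",
         paste(classes, collapse = ", "))
  }
  if (is.null(positive)) positive <- if ("nano" %in% classes) "nano" else classes[1]
  if (!(positive %in% classes)) stop("positive class not present in labels")
  negative <- setdiff(classes, positive)
  y01 <- as.integer(labels == positive)

  fit <- .with_seed(spec$seed, switch(
    spec$family,
    mnb = .fit_mnb(X, y01, spec),
    c45 = .fit_tree(X, y01, spec, positive, negative),
    sgd_logreg = .fit_sgd(X, y01, spec),
    l1_logreg = .fit_glmnet(X, y01, spec, alpha = 1),
    l2_logreg = .fit_glmnet(X, y01, spec, alpha = 0),
    svm_linear = .fit_svm(X, y01, spec, kernel = "linear"),
    svm_poly2 = .fit_svm(X, y01, spec, kernel = "polynomial")
  ))

  structure(
    list(spec = spec, family = spec$family, fit = fit,
         features = colnames(X), n_features = ncol(X),
         positive = positive, negative = negative,
         score_type = if (spec$family %in% c("svm_linear", "svm_poly2"))
           "margin" else "probability"),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model>", x$family, "on", x$n_features, "features; positive =",
      x$positive, paste0("(", x$score_type, " scores)\n"))
  invisible(x)
}

.fit_mnb <- function(X, y01, spec) {
  if (any(X@x < 0)) stop("multinomial naive Bayes requires nonnegative features")
  p <- ncol(X)
  n <- nrow(X)
  counts_pos <- Matrix::colSums(X[y01 == 1L, , drop = FALSE])
  counts_neg <- Matrix::colSums(X[y01 == 0L, , drop = FALSE])
  log_theta_pos <- log(spec$alpha + counts_pos) -
    log(spec$alpha * p + sum(counts_pos))
  log_theta_neg <- log(spec$alpha + counts_neg) -
    log(spec$alpha * p + sum(counts_neg))
  list(log_prior_delta = log(sum(y01 == 1L) / n) - log(sum(y01 == 0L) / n),
       log_theta_delta = as.numeric(log_theta_pos - log_theta_neg))
}

.fit_tree <- function(X, y01, spec, positive, negative) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.label <- factor(ifelse(y01 == 1L, positive, negative),
                      levels = c(negative, positive))
  rpart::rpart(.label ~ ., data = df, method = "class",
               control = rpart::rpart.control(cp = spec$tree_cp,
                                              minsplit = spec$tree_minsplit,
                                              xval = 0))
}

.fit_sgd <- function(X, y01, spec) {
  n <- nrow(X)
  p <- ncol(X)
  Xt <- methods::as(X, "TsparseMatrix")
  row_j <- split(Xt@j + 1L, factor(Xt@i + 1L, levels = seq_len(n)))
  row_x <- split(Xt@x, factor(Xt@i + 1L, levels = seq_len(n)))
  w <- numeric(p)
  b <- 0
  t <- 0L
  for (ep in seq_len(spec$epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1L
      eta <- spec$learning_rate / (1 + spec$learning_rate * spec$sgd_lambda * t)
      j <- row_j[[i]]
      z <- b + if (length(j)) sum(w[j] * row_x[[i]]) else 0
      g <- stats::plogis(z) - y01[i]
      w <- w * (1 - eta * spec$sgd_lambda)
      if (length(j)) w[j] <- w[j] - eta * g * row_x[[i]]
      b <- b - eta * g
    }
  }
  list(w = w, b = b)
}

.fit_glmnet <- function(X, y01, spec, alpha) {
  Xg <- X
  padded <- FALSE
  if (ncol(Xg) < 2L) {  # glmnet requires >= 2 predictors
    Xg <- cbind(Xg, Matrix::Matrix(0, nrow(Xg), 1, sparse = TRUE))
    padded <- TRUE
  }
  lam_path <- spec$lambda * 10^seq(2, 0, length.out = 15)
  fit <- withCallingHandlers(
    glmnet::glmnet(Xg, factor(y01, levels = c(0L, 1L)),
                   family = "binomial", alpha = alpha,
                   lambda = lam_path, standardize = FALSE),
    warning = function(w) {
      # benign at leave-one-out / toy sizes
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(glmnet = fit, lambda = spec$lambda, padded = padded)
}

.fit_svm <- function(X, y01, spec, kernel) {
  y <- factor(ifelse(y01 == 1L, "pos", "neg"), levels = c("pos", "neg"))
  e1071::svm(x = as.matrix(X), y = y, kernel = kernel,
             degree = if (kernel == "polynomial") 2L else 3L,
             gamma = 1, coef0 = 0, cost = spec$cost, scale = FALSE)
}

# align a score-time matrix with the training feature space
.align_features <- function(X, model) {
  if (!is.null(colnames(X)) && !is.null(model$features)) {
    if (identical(colnames(X), model$features)) return(X)
    if (setequal(colnames(X), model$features) &&
        ncol(X) == model$n_features) {
      return(X[, model$features, drop = FALSE])
    }
    stop("feature dimension mismatch: matrix features differ from the ",
         "training vocabulary")
  }
  if (ncol(X) != model$n_features) {
    stop("feature dimension mismatch: expected ", model$n_features,
         " features, got ", ncol(X))
  }
  X
}

#' Score documents with a trained model
#'
#' Higher scores mean more positive-class-like. Logistic families and
#' multinomial naive Bayes return probabilities in (0, 1); SVM families
#' return the signed margin; the decision tree returns the leaf proportion of
#' the positive class.
#'
#' @param model a [train_model()] result.
#' @param x documents to score: a `doc_term_matrix`, matrix, sparse matrix or
#'   a single named numeric vector (e.g. from [apply_vocabulary()]). Feature
#'   space must match the training vocabulary.
#' @return numeric vector of positive-class scores.
#' @export
score_model <- function(model, x) {
  X <- .align_features(.as_feature_matrix(x), model)
  out <- switch(
    model$family,
    mnb = {
      z <- as.numeric(X %*% model$fit$log_theta_delta) +
        model$fit$log_prior_delta
      stats::plogis(z)
    },
    c45 = {
      df <- as.data.frame(as.matrix(X))
      names(df) <- paste0("f", seq_len(ncol(df)))
      pr <- stats::predict(model$fit, newdata = df, type = "prob")
      as.numeric(pr[, model$positive])
    },
    sgd_logreg = stats::plogis(as.numeric(X %*% model$fit$w) + model$fit$b),
    l1_logreg = ,
    l2_logreg = {
      Xg <- if (model$fit$padded) {
        cbind(X, Matrix::Matrix(0, nrow(X), 1, sparse = TRUE))
      } else X
      as.numeric(stats::predict(model$fit$glmnet, newx = Xg,
                                s = model$fit$lambda, type = "response"))
    },
    svm_linear = ,
    svm_poly2 = {
      pr <- stats::predict(model$fit, newdata = as.matrix(X),
                           decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sgn <- if (colnames(dv)[1] == "pos/neg") 1 else -1
      sgn * as.numeric(dv[, 1])
    }
  )
  stats::setNames(out, rownames(X))
}

#' Predict hard class labels
#'
#' Thresholds [score_model()] scores; a score exactly at the threshold is
#' assigned to the positive class.
#'
#' @inheritParams score_model
#' @param threshold decision threshold; defaults to 0.5 for
#'   probability-scoring families and 0 for margin-scoring (SVM) families.
#' @return character vector of predicted labels.
#' @export
predict_model <- function(model, x, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- if (model$score_type == "margin") 0 else 0.5
  }
  s <- score_model(model, x)
  stats::setNames(ifelse(s >= threshold, model$positive, model$negative),
                  names(s))
}

#' Coefficients of a linear model
#'
#' @param model a trained `sgd_logreg`, `l1_logreg`, `l2_logreg` or
#'   `svm_linear` model.
#' @return list with `weights` (named numeric vector over the training
#'   features) and `intercept`.
#' @export
model_weights <- function(model) {
  out <- switch(
    model$family,
    sgd_logreg = list(weights = model$fit$w, intercept = model$fit$b),
    l1_logreg = ,
    l2_logreg = {
      beta <- stats::coef(model$fit$glmnet, s = model$fit$lambda)
      w <- as.numeric(beta)[-1]
      if (model$fit$padded) w <- w[seq_len(model$n_features)]
      list(weights = w, intercept = as.numeric(beta)[1])
    },
    svm_linear = {
      w <- as.numeric(crossprod(model$fit$coefs, model$fit$SV))
      sgn <- if (model$fit$levels[1] == "pos") 1 else -1
      list(weights = sgn * w, intercept = sgn * -model$fit$rho)
    },
    stop("model_weights is defined for linear families only, not ",
         model$family)
  )
  names(out$weights) <- model$features
  out
}
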