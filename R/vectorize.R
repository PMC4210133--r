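#' Build a vocabulary from feature bags
#'
#' The vocabulary is the lexicographically sorted union of all bag features,
#' together with each feature's document frequency df(t) (number of documents
#' containing it) and the corpus size N. Inverse document frequency is
#' idf(t) = ln(N / df(t)), so a feature present in every document gets weight
#' exactly 0 and drops out of the IDF and TF-IDF representations.
#'
#' @param bags list of feature bags (named integer vectors).
#' @return a `vocabulary`: list with `features` (sorted), `df` (named integer
#'   vector) and `n_docs`.
#' @export
build_vocabulary <- function(bags) {
  if (length(bags) == 0L) stop("empty corpus: no feature bags")
  present <- unlist(lapply(bags, names), use.names = FALSE)
  df_tab <- table(present)
  features <- sort(names(df_tab), method = "radix")
  structure(
    list(features = features,
         df = stats::setNames(as.integer(df_tab[features]), features),
         n_docs = length(bags)),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$features), " features over ",
      x$n_docs, " documents\n", sep = "")
  invisible(x)
}

#' Inverse document frequencies of a vocabulary
#'
#' @param vocab a [build_vocabulary()] result.
#' @return named numeric vector, `ln(N / df)` per feature.
#' @export
idf_weights <- function(vocab) {
  log(vocab$n_docs / vocab$df)
}

# entry weight for one (tf, df) pair under a scheme
.scheme_weight <- function(tf, df, n_docs, scheme) {
  switch(scheme,
         binary = rep(1, length(tf)),
         frequency = as.numeric(tf),
         idf = log(n_docs / df),
         tfidf = as.numeric(tf) * log(n_docs / df),
         stop("unknown scheme: ", scheme))
}

#' Weight feature bags into a document-term matrix
#'
#' Builds the sparse documents-by-features matrix under one of the four
#' bag-of-words representations:
#' \describe{
#'   \item{binary}{1 if the feature occurs in the document, else 0;}
#'   \item{frequency}{the within-document term frequency tf(t, d);}
#'   \item{idf}{idf(t) = ln(N/df(t)) wherever the feature occurs (presence
#'     weighted by global rarity, term frequency ignored);}
#'   \item{tfidf}{tf(t, d) * idf(t).}
#' }
#' With `normalize = TRUE` each row is scaled to unit Euclidean norm
#' (all-zero rows are left as zero). Bag features absent from `vocab` are
#' dropped, which is how held-out documents are projected onto a training
#' vocabulary without information leaking back.
#'
#' @param bags list of feature bags.
#' @param vocab a [build_vocabulary()] result; defaults to the vocabulary of
#'   `bags` themselves. In cross-validation pass the training-split
#'   vocabulary.
#' @param scheme one of `"binary"`, `"frequency"`, `"idf"`, `"tfidf"`.
#' @param normalize scale each document vector by its L2 norm.
#' @return a `doc_term_matrix`: list with `matrix` (a
#'   [Matrix::dgCMatrix-class], documents in rows), `scheme`, `normalized`
#'   and `vocabulary`.
#' @export
weight_matrix <- function(bags, vocab = build_vocabulary(bags),
                          scheme = c("binary", "frequency", "idf", "tfidf"),
                          normalize = FALSE) {
  scheme <- match.arg(scheme)
  n <- length(bags)
  p <- length(vocab$features)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_len(n)) {
    b <- bags[[d]]
    j <- match(names(b), vocab$features)
    keep <- !is.na(j)
    if (!any(keep)) next
    j <- j[keep]
    tf <- as.numeric(b[keep])
    w <- .scheme_weight(tf, vocab$df[j], vocab$n_docs, scheme)
    ii <- c(ii, rep.int(d, length(j)))
    jj <- c(jj, j)
    xx <- c(xx, w)
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, p),
                            dimnames = list(names(bags), vocab$features))
  m <- Matrix::drop0(m)
  if (normalize) m <- .l2_normalize_rows(m)
  structure(
    list(matrix = m, scheme = scheme, normalized = normalize,
         vocabulary = vocab),
    class = "doc_term_matrix"
  )
}

.l2_normalize_rows <- function(m) {
  norms <- sqrt(Matrix::rowSums(m^2))
  scale <- ifelse(norms > 0, 1 / norms, 0)
  out <- Matrix::Diagonal(x = scale) %*% m
  dimnames(out) <- dimnames(m)
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' @export
print.doc_term_matrix <- function(x, ...) {
  cat("<doc_term_matrix> ", nrow(x$matrix), " documents x ", ncol(x$matrix),
      " features, scheme=", x$scheme,
      if (x$normalized) ", L2-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.doc_term_matrix <- function(x) dim(x$matrix)

#' Project a held-out document onto a training vocabulary
#'
#' Applies the same weighting as [weight_matrix()] using the training
#' vocabulary's N and df; features unseen in training are ignored.
#'
#' @param bag a single feature bag.
#' @param vocab the training-split vocabulary.
#' @inheritParams weight_matrix
#' @return named numeric vector of length `length(vocab$features)`.
#' @export
apply_vocabulary <- function(bag, vocab,
                             scheme = c("binary", "frequency", "idf", "tfidf"),
                             normalize = FALSE) {
  scheme <- match.arg(scheme)
  dtm <- weight_matrix(list(doc = bag), vocab, scheme, normalize)
  stats::setNames(as.numeric(dtm$matrix[1L, ]), vocab$features)
}
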