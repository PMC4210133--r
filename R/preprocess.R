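#' Split text into raw tokens
#'
#' Tokens are maximal runs of alphanumeric characters or underscores; every
#' other character (blanks, punctuation, hyphens) separates tokens. Empty
#' fragments are dropped and order is preserved.
#'
#' @param text a single character string.
#' @return character vector of raw tokens.
#' @examples
#' tokenize("Doxil (liposomal doxorubicin), 50 mg.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(text, "[^A-Za-z0-9_]+")[[1]]
  toks[nzchar(toks)]
}

#' The packaged English stop-word list
#'
#' A frozen copy of a standard English stop-word list is shipped with the
#' package so that results do not drift with external library versions.
#'
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "nanoct",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

#' Normalize a raw token stream
#'
#' Applies the fixed preprocessing pipeline, in this order:
#' \enumerate{
#'   \item every decimal digit is replaced by `'#'` (so numbers contribute a
#'     shape feature, not a value);
#'   \item all text is lowercased;
#'   \item stop words are removed;
#'   \item tokens shorter than three characters are removed (the length filter
#'     runs after masking, so `"100"` survives as `"###"`);
#'   \item survivors are Porter-stemmed (stems shorter than three characters
#'     may result; the length filter applies to pre-stem tokens).
#' }
#'
#' @param tokens character vector of raw tokens (from [tokenize()]).
#' @param stopwords character vector of stop words; compared after
#'   lowercasing.
#' @return character vector of normalized tokens, order preserved.
#' @examples
#' normalize_tokens(c("Doxil", "liposomal", "doxorubicin", "50", "mg"))
#' @export
normalize_tokens <- function(tokens, stopwords = default_stopwords()) {
  if (length(tokens) == 0L) return(character(0))
  toks <- tolower(gsub("[0-9]", "#", tokens))
  toks <- toks[!(toks %in% stopwords)]
  toks <- toks[nchar(toks) >= 3L]
  porter_stem(toks)
}

#' Extract n-gram counts from a normalized token stream
#'
#' Unigrams are single tokens; bigrams are ordered pairs of adjacent tokens
#' joined by a single space (a character that cannot occur inside a token).
#'
#' @param tokens character vector of normalized tokens.
#' @param n 1 or 2.
#' @return named integer vector of within-document feature counts (a feature
#'   bag); empty when fewer than `n` tokens are available.
#' @export
extract_ngrams <- function(tokens, n = 1L) {
  if (!(n %in% c(1L, 2L))) stop("`n` must be 1 or 2")
  if (length(tokens) < n) return(stats::setNames(integer(0), character(0)))
  feats <- if (n == 1L) {
    tokens
  } else {
    paste(tokens[-length(tokens)], tokens[-1L])
  }
  tab <- table(feats)
  stats::setNames(as.integer(tab), names(tab))
}

#' Turn one document's text into a feature bag
#'
#' Runs [tokenize()], [normalize_tokens()] and [extract_ngrams()] per text
#' segment. Newlines in the text are hard segment boundaries (record fields
#' are newline-joined), so bigrams never pair tokens from different fields.
#'
#' @param text a single character string.
#' @param n 1 or 2.
#' @param stopwords passed to [normalize_tokens()].
#' @return named integer vector of feature counts.
#' @export
document_features <- function(text, n = 1L, stopwords = default_stopwords()) {
  segments <- strsplit(text, "\n", fixed = TRUE)[[1]]
  segments <- segments[nzchar(segments)]
  if (length(segments) == 0L) return(stats::setNames(integer(0), character(0)))
  bags <- lapply(segments, function(s) {
    extract_ngrams(normalize_tokens(tokenize(s), stopwords), n)
  })
  all <- unlist(bags, use.names = TRUE)
  if (length(all) == 0L) return(stats::setNames(integer(0), character(0)))
  tot <- tapply(all, names(all), sum)
  stats::setNames(as.integer(tot), names(tot))
}

#' Feature bags for every document of a corpus
#'
#' @param corpus a [labeled_corpus()].
#' @inheritParams document_features
#' @return named list of feature bags, one per record, named by `nct_id`.
#' @export
corpus_features <- function(corpus, n = 1L, stopwords = default_stopwords()) {
  bags <- lapply(corpus$text, document_features, n = n, stopwords = stopwords)
  names(bags) <- corpus$nct_id
  bags
}

#' Corpus-level feature statistics
#'
#' Summarizes per-document feature totals (with double-counting) and unique
#' feature counts (without), plus the global feature inventory and the mean
#' number of documents each feature occurs in.
#'
#' @param bags list of feature bags (from [corpus_features()]).
#' @return list with elements `n_docs`, `per_document` (data frame with
#'   `total` and `unique` per document), `summary` (min/max/mean/sd for both
#'   counts), `n_features` and `mean_document_frequency`.
#' @export
corpus_feature_stats <- function(bags) {
  if (length(bags) == 0L) stop("empty corpus: no feature bags")
  totals <- vapply(bags, function(b) sum(as.numeric(b)), numeric(1))
  uniques <- vapply(bags, length, integer(1))
  df <- table(unlist(lapply(bags, names), use.names = FALSE))
  stat <- function(x) c(min = min(x), max = max(x),
                        mean = mean(x), sd = stats::sd(x))
  sd0 <- function(s) { if (is.na(s["sd"])) s["sd"] <- 0; s }
  list(
    n_docs = length(bags),
    per_document = data.frame(total = totals, unique = uniques,
                              row.names = names(bags)),
    summary = rbind(total = sd0(stat(totals)), unique = sd0(stat(uniques))),
    n_features = length(df),
    mean_document_frequency = if (length(df)) mean(as.integer(df)) else NA_real_
  )
}
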