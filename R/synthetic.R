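# integer -> fixed-width lowercase letter code ("aaa", "aab", ...)
.letter_code <- function(i, width = 4L) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k] - 1L
    chars <- character(width)
    for (pos in width:1) {
      chars[pos] <- letters[v %% 26L + 1L]
      v <- v %/% 26L
    }
    out[k] <- paste(chars, collapse = "")
  }
  out
}

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates a balanced two-class corpus of trial-summary-like
#' documents: per-document token counts follow a floored log-normal whose
#' target mean/sd default to the real corpus's document-length statistics
#' (mean 732, sd 1001 tokens, minimum 111); the shared background vocabulary
#' is drawn from a Zipf distribution (giving realistic document-frequency
#' skew); and the two classes differ only through sparse, token-level
#' injection of class-specific terms — each emitted token is a term of the
#' document's own class with probability `injection_rate`, a term of the
#' other class with probability `cross_rate`, and a background draw
#' otherwise.
#'
#' @param n_per_class documents per class (default 500, a balanced
#'   1000-document corpus).
#' @param background_vocab_size background vocabulary size (default 2000).
#' @param zipf_exponent exponent of the background rank-frequency law
#'   (default 1.1).
#' @param n_discriminative class-specific terms per class (default 20).
#' @param injection_rate per-token probability of an own-class term
#'   (default 0.05).
#' @param cross_rate per-token probability of an other-class term
#'   (default 0).
#' @param length_mean,length_sd target mean and sd of tokens per document
#'   (defaults 732 and 1001).
#' @param length_floor minimum document length in tokens (default 111).
#' @param seed integer seed; the same seed yields a byte-identical corpus.
#' @return a `generator_config`.
#' @export
generator_config <- function(n_per_class = 500L, background_vocab_size = 2000L,
                             zipf_exponent = 1.1, n_discriminative = 20L,
                             injection_rate = 0.05, cross_rate = 0,
                             length_mean = 732, length_sd = 1001,
                             length_floor = 111L, seed = 1L) {
  if (injection_rate < 0 || injection_rate > 1 || cross_rate < 0 ||
      cross_rate > 1 || injection_rate + cross_rate > 1) {
    stop("injection_rate and cross_rate must lie in [0, 1] and sum to <= 1")
  }
  if (length_floor < 1) stop("length_floor must be >= 1")
  if (background_vocab_size < 1 || n_per_class < 1) {
    stop("vocabulary and class sizes must be >= 1")
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         background_vocab_size = as.integer(background_vocab_size),
         zipf_exponent = zipf_exponent,
         n_discriminative = as.integer(n_discriminative),
         injection_rate = injection_rate, cross_rate = cross_rate,
         length_mean = length_mean, length_sd = length_sd,
         length_floor = as.integer(length_floor), seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a labeled synthetic corpus
#'
#' Documents are emitted as space-joined token text in `ct_record` shape
#' (ids `NCT90000001`, ...), so the full pipeline — preprocessing,
#' vectorization, classification, validation — runs on them unmodified.
#' Tokens are lowercase alphabetic with length >= 3 and avoid stop words, so
#' normalization is a near-no-op on them. The ground-truth discriminative
#' term sets are attached for recovery tests.
#'
#' @param config a [generator_config()].
#' @return a `synthetic_corpus` (a [labeled_corpus()] with attributes
#'   `truth_terms` — list with the `nano` and `non-nano` term sets — and
#'   `config`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_bg <- config$background_vocab_size
  n_disc <- config$n_discriminative
  background <- paste0("bkg", .letter_code(seq_len(n_bg)))
  terms_nano <- if (n_disc > 0) paste0("nanosig", .letter_code(seq_len(n_disc), 3L)) else character(0)
  terms_ctrl <- if (n_disc > 0) paste0("ctrlsig", .letter_code(seq_len(n_disc), 3L)) else character(0)

  p_bg <- seq_len(n_bg)^(-config$zipf_exponent)
  p_bg <- p_bg / sum(p_bg)

  class_prob <- function(own_rate, other_rate) {
    c(p_bg * (1 - own_rate - other_rate),
      rep(own_rate / max(n_disc, 1L), n_disc),
      rep(other_rate / max(n_disc, 1L), n_disc))
  }
  tokens_nano <- c(background, terms_nano, terms_ctrl)
  tokens_ctrl <- c(background, terms_ctrl, terms_nano)
  prob_nano <- class_prob(config$injection_rate, config$cross_rate)
  prob_ctrl <- prob_nano  # same mixture shape, own/other swapped via tokens

  # log-normal parameters matching the target mean/sd by moments
  sigma2 <- log(1 + (config$length_sd / config$length_mean)^2)
  mu <- log(config$length_mean) - sigma2 / 2

  n <- 2L * config$n_per_class
  labels <- rep(c("nano", "non-nano"), each = config$n_per_class)
  texts <- character(n)
  .with_seed(config$seed, {
    lens <- pmax(config$length_floor,
                 as.integer(round(stats::rlnorm(n, mu, sqrt(sigma2)))))
    for (d in seq_len(n)) {
      if (labels[d] == "nano") {
        toks <- sample(tokens_nano, lens[d], replace = TRUE, prob = prob_nano)
      } else {
        toks <- sample(tokens_ctrl, lens[d], replace = TRUE, prob = prob_ctrl)
      }
      texts[d] <- paste(toks, collapse = " ")
    }
  })

  corpus <- labeled_corpus(sprintf("NCT9%07d", seq_len(n)), texts, labels)
  attr(corpus, "truth_terms") <- list("nano" = terms_nano,
                                      "non-nano" = terms_ctrl)
  attr(corpus, "config") <- config
  class(corpus) <- c("synthetic_corpus", class(corpus))
  corpus
}

#' Ground-truth discriminative terms of a synthetic corpus
#'
#' @param corpus a [generate_corpus()] result.
#' @return list with the `nano` and `non-nano` term sets.
#' @export
truth_terms <- function(corpus) {
  tt <- attr(corpus, "truth_terms")
  if (is.null(tt)) stop("corpus carries no ground-truth terms")
  tt
}

#' Check a synthetic corpus against its configured length model
#'
#' @param corpus a [generate_corpus()] result.
#' @param config the [generator_config()] it was generated from.
#' @param tol relative tolerance on mean and sd (default 0.15).
#' @return list with `mean`, `sd`, `min`, `max` of per-document token counts,
#'   the configured targets and `within_tolerance`.
#' @export
length_stats_check <- function(corpus, config = attr(corpus, "config"),
                               tol = 0.15) {
  lens <- vapply(corpus$text, function(t) length(tokenize(t)), integer(1),
                 USE.NAMES = FALSE)
  ok <- abs(mean(lens) - config$length_mean) <= tol * config$length_mean &&
    abs(stats::sd(lens) - config$length_sd) <= tol * config$length_sd
  list(mean = mean(lens), sd = stats::sd(lens),
       min = min(lens), max = max(lens),
       target_mean = config$length_mean, target_sd = config$length_sd,
       floor = config$length_floor, within_tolerance = ok)
}
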