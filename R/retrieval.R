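#' Construct a term list for dictionary-based retrieval
#'
#' A term list groups surface terms (synonyms) under concept identifiers,
#' e.g. concepts exported from a biomedical metathesaurus. Terms are matched
#' against raw document text (before stemming or masking), because dictionary
#' entries are surface forms.
#'
#' @param concept_id character vector of concept identifiers.
#' @param term parallel character vector of terms; trimmed, must be non-empty.
#' @param provenance free-text note on where the list came from.
#' @return a `term_list` (data frame with columns `concept_id`, `term`).
#' @export
term_list <- function(concept_id, term, provenance = NA_character_) {
  if (length(concept_id) != length(term)) {
    stop("concept_id and term must have equal length")
  }
  term <- trimws(term)
  if (length(term) == 0L) stop("empty term list")
  if (any(!nzchar(term))) stop("terms must be non-empty after trimming")
  structure(
    data.frame(concept_id = as.character(concept_id), term = term,
               stringsAsFactors = FALSE),
    provenance = provenance,
    class = c("term_list", "data.frame")
  )
}

#' Read a term list from a tab-separated file
#'
#' Expected layout: UTF-8 text, one `concept_id<TAB>term` row per term;
#' synonyms share a `concept_id`. A header row `concept_id<TAB>term` is
#' skipped if present.
#'
#' @param path file path.
#' @return a [term_list()].
#' @export
read_term_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^concept_id\tterm$", lines[1])) {
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop("empty term list")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) stop("malformed term-list row(s): ",
                     paste(lines[bad], collapse = "; "))
  term_list(vapply(parts, `[[`, character(1), 1L),
            vapply(parts, function(p) paste(p[-1L], collapse = "\t"), character(1)),
            provenance = path)
}

# case-folded surface tokens; hyphens and punctuation separate tokens
.match_tokens <- function(text) tokenize(tolower(text))

# occurrences of a token sequence in a token vector; in prefix mode the last
# element of the sequence matches any token it prefixes
.count_seq <- function(tokens, seq, prefix = FALSE) {
  L <- length(seq)
  n <- length(tokens)
  if (n < L || L == 0L) return(0L)
  last_ok <- if (prefix) startsWith(tokens, seq[L]) else tokens == seq[L]
  if (L == 1L) return(sum(last_ok))
  starts <- which(tokens == seq[1L])
  starts <- starts[starts <= n - L + 1L]
  hits <- 0L
  for (s in starts) {
    mid <- L == 2L || all(tokens[(s + 1L):(s + L - 2L)] == seq[2:(L - 1L)])
    if (mid && last_ok[s + L - 1L]) hits <- hits + 1L
  }
  hits
}

#' Match a dictionary of terms against a corpus
#'
#' Matching is case-insensitive and operates on the raw surface token stream
#' (punctuation and hyphens act as token separators), emulating keyword
#' searches against a registry's own search engine. Three modes:
#' \describe{
#'   \item{token}{a term matches where its token sequence occurs verbatim
#'     (a single-word term matches equal tokens);}
#'   \item{phrase}{identical to token matching for multiword terms, named
#'     separately for clarity of intent;}
#'   \item{prefix}{the term's final token matches any token it is a prefix of
#'     (e.g. term "nano" matches "nanosuspension") — the capability public
#'     registry search lacks.}
#' }
#'
#' @param corpus a [labeled_corpus()] (labels are ignored).
#' @param terms a [term_list()].
#' @param mode one of `"token"`, `"phrase"`, `"prefix"`.
#' @return a `match_report`: list with `matches` (data frame `nct_id`,
#'   `concept_id`, `term`, `n_hits`, one row per record/term with at least one
#'   hit), `matched_ids`, `n_concepts_matched` and `mode`.
#' @export
match_terms <- function(corpus, terms, mode = c("token", "phrase", "prefix")) {
  mode <- match.arg(mode)
  if (!inherits(terms, "term_list") || nrow(terms) == 0L) {
    stop("empty term list")
  }
  term_seqs <- lapply(terms$term, .match_tokens)
  usable <- vapply(term_seqs, length, integer(1)) > 0L
  if (!any(usable)) stop("no usable terms after tokenization")
  doc_tokens <- lapply(corpus$text, .match_tokens)
  prefix <- mode == "prefix"

  rows <- vector("list", nrow(corpus))
  for (d in seq_len(nrow(corpus))) {
    toks <- doc_tokens[[d]]
    hits <- vapply(seq_along(term_seqs), function(i) {
      if (!usable[i]) return(0L)
      .count_seq(toks, term_seqs[[i]], prefix = prefix)
    }, integer(1))
    hit <- hits > 0L
    if (any(hit)) {
      rows[[d]] <- data.frame(nct_id = corpus$nct_id[d],
                              concept_id = terms$concept_id[hit],
                              term = terms$term[hit],
                              n_hits = hits[hit],
                              stringsAsFactors = FALSE)
    }
  }
  matches <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(matches)) {
    matches <- data.frame(nct_id = character(0), concept_id = character(0),
                          term = character(0), n_hits = integer(0))
  }
  structure(
    list(matches = matches,
         matched_ids = unique(matches$nct_id),
         n_concepts_matched = length(unique(matches$concept_id)),
         mode = mode),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> mode=", x$mode, ": ", length(x$matched_ids),
      " record(s) matched, ", x$n_concepts_matched, " concept(s)\n", sep = "")
  invisible(x)
}

#' Propose candidate records from a match report
#'
#' Records matching at least `min_concepts` distinct concepts are proposed
#' as candidates for human review.
#'
#' @param report a `match_report` from [match_terms()].
#' @param min_concepts minimum number of distinct matched concepts.
#' @return sorted character vector of candidate `nct_id`s.
#' @export
propose_candidates <- function(report, min_concepts = 1L) {
  m <- report$matches
  if (nrow(m) == 0L) return(character(0))
  per_record <- tapply(m$concept_id, m$nct_id,
                       function(cc) length(unique(cc)))
  sort(names(per_record)[per_record >= min_concepts])
}
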