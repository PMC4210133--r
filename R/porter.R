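#' Porter stemming for English
#'
#' Reduces inflected English words to a common stem with Porter's
#' suffix-stripping algorithm (the original five-step rule set). Stemming is
#' the final preprocessing stage applied to corpus tokens, grouping words of
#' the same family ("nanoparticle", "nanoparticles") under one feature.
#'
#' Input is lowercased before stemming. Words shorter than three characters
#' are returned unchanged. Non-alphabetic characters are treated as
#' consonants, so masked-digit tokens such as `"###"` pass through untouched.
#'
#' @param words character vector of tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("nanoparticles", "liposomal", "studies"))
#' @export
porter_stem <- function(words) {
  if (!is.character(words)) stop("`words` must be a character vector")
  words <- tolower(words)
  if (length(words) == 0L) return(character(0))
  # stem each distinct word once; corpora repeat tokens heavily
  uw <- unique(words)
  stems <- vapply(uw, .porter_word, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

# consonant/vowel classification: a,e,i,o,u vowels; y is a consonant at the
# start of the word or after a vowel, otherwise a vowel
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  for (i in seq_len(n)) {
    if (chars[i] == "y") cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
  }
  cons
}

# the measure m: number of vowel-run -> consonant-run transitions
.porter_m <- function(chars) {
  if (length(chars) == 0L) return(0L)
  runs <- rle(.porter_cons(chars))$values
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1L])
}

.porter_has_vowel <- function(chars) {
  length(chars) > 0L && any(!.porter_cons(chars))
}

.porter_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && .porter_cons(chars)[n]
}

# *o: ends consonant-vowel-consonant where the final consonant is not w, x, y
.porter_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  cons <- .porter_cons(chars)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(chars[n] %in% c("w", "x", "y"))
}

# longest-suffix rule application for steps 2-4: at most one rule fires
.porter_rules <- function(word, chars, suffixes, repl, min_m) {
  hit <- 0L
  hit_len <- -1L
  n <- nchar(word)
  for (i in seq_along(suffixes)) {
    sl <- nchar(suffixes[i])
    if (sl > hit_len && n > sl && substring(word, n - sl + 1L) == suffixes[i]) {
      hit <- i
      hit_len <- sl
    }
  }
  if (hit == 0L) return(word)
  stem_chars <- chars[seq_len(n - hit_len)]
  if (.porter_m(stem_chars) > min_m) {
    paste0(substring(word, 1L, n - hit_len), repl[hit])
  } else {
    word
  }
}

.porter_word <- function(word) {
  if (nchar(word) < 3L) return(word)
  ends <- function(s) {
    sl <- nchar(s)
    nchar(word) >= sl && substring(word, nchar(word) - sl + 1L) == s
  }
  chop <- function(k) substring(word, 1L, nchar(word) - k)
  wchars <- function() strsplit(word, "", fixed = TRUE)[[1]]

  ## step 1a
  if (ends("sses")) word <- chop(2L)
  else if (ends("ies")) word <- chop(2L)
  else if (!ends("ss") && ends("s")) word <- chop(1L)

  ## step 1b
  fired <- FALSE
  if (ends("eed")) {
    if (.porter_m(strsplit(chop(3L), "", fixed = TRUE)[[1]]) > 0L) word <- chop(1L)
  } else if (ends("ed") &&
             .porter_has_vowel(strsplit(chop(2L), "", fixed = TRUE)[[1]])) {
    word <- chop(2L); fired <- TRUE
  } else if (ends("ing") &&
             .porter_has_vowel(strsplit(chop(3L), "", fixed = TRUE)[[1]])) {
    word <- chop(3L); fired <- TRUE
  }
  if (fired) {
    if (ends("at") || ends("bl") || ends("iz")) {
      word <- paste0(word, "e")
    } else {
      ch <- wchars()
      if (.porter_double_cons(ch) && !(ch[length(ch)] %in% c("l", "s", "z"))) {
        word <- chop(1L)
      } else if (.porter_m(ch) == 1L && .porter_cvc(ch)) {
        word <- paste0(word, "e")
      }
    }
  }

  ## step 1c
  if (ends("y") && .porter_has_vowel(strsplit(chop(1L), "", fixed = TRUE)[[1]])) {
    word <- paste0(chop(1L), "i")
  }

  ## step 2 (m > 0)
  word <- .porter_rules(
    word, wchars(),
    c("ational", "tional", "enci", "anci", "izer", "abli", "alli", "entli",
      "eli", "ousli", "ization", "ation", "ator", "alism", "iveness",
      "fulness", "ousness", "aliti", "iviti", "biliti"),
    c("ate", "tion", "ence", "ance", "ize", "able", "al", "ent",
      "e", "ous", "ize", "ate", "ate", "al", "ive",
      "ful", "ous", "al", "ive", "ble"),
    min_m = 0L
  )

  ## step 3 (m > 0)
  word <- .porter_rules(
    word, wchars(),
    c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    c("ic", "", "al", "ic", "ic", "", ""),
    min_m = 0L
  )

  ## step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  n <- nchar(word)
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
          "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  hit <- 0L; hit_len <- -1L
  for (i in seq_along(s4)) {
    sl <- nchar(s4[i])
    if (sl > hit_len && n > sl && substring(word, n - sl + 1L) == s4[i]) {
      hit <- i; hit_len <- sl
    }
  }
  if (hit > 0L) {
    stem <- substring(word, 1L, n - hit_len)
    stem_chars <- strsplit(stem, "", fixed = TRUE)[[1]]
    ok <- .porter_m(stem_chars) > 1L
    if (ok && s4[hit] == "ion") {
      last <- stem_chars[length(stem_chars)]
      ok <- last %in% c("s", "t")
    }
    if (ok) word <- stem
  }

  ## step 5a
  if (ends("e")) {
    stem_chars <- strsplit(chop(1L), "", fixed = TRUE)[[1]]
    m <- .porter_m(stem_chars)
    if (m > 1L || (m == 1L && !.porter_cvc(stem_chars))) word <- chop(1L)
  }

  ## step 5b
  ch <- wchars()
  if (.porter_m(ch) > 1L && .porter_double_cons(ch) && ch[length(ch)] == "l") {
    word <- chop(1L)
  }

  word
}
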