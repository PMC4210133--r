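test_that("tokenization splits on blanks and punctuation, keeps underscores", {
  expect_equal(tokenize("Doxil (liposomal doxorubicin), 50 mg."),
               c("Doxil", "liposomal", "doxorubicin", "50", "mg"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("nano_drug"), "nano_drug")
  expect_equal(tokenize("iron-oxide"), c("iron", "oxide"))
})

test_that("normalization applies digit masking, case, stop words, length, stemming in order", {
  expect_equal(normalize_tokens(c("Doxil", "liposomal", "doxorubicin", "50", "mg")),
               c("doxil", "liposom", "doxorubicin"))
  expect_equal(normalize_tokens(c("The", "AND", "of")), character(0))
  expect_equal(normalize_tokens("Nanoparticles"), "nanoparticl")
  # masking precedes the length filter: "100" survives as "###", "50" does not
  expect_equal(normalize_tokens(c("100", "50")), "###")
  # full pipeline on a hand-worked sentence
  toks <- tokenize("The Study of 100 Nanoparticles and nano-gels, 50 mg")
  expect_equal(normalize_tokens(toks),
               c("studi", "###", "nanoparticl", "nano", "gel"))
})

test_that("Porter stemming matches the reference word list", {
  words <- c("caresses", "ponies", "ties", "caress", "cats", "feed", "agreed",
             "plastered", "bled", "motoring", "sing", "conflated", "troubled",
             "sized", "hopping", "tanned", "falling", "hissing", "fizzed",
             "failing", "filing", "happy", "sky", "relational", "conditional",
             "rational", "electricity", "electrical", "hopefulness",
             "goodness", "revival", "adjustable", "defensible", "irritant",
             "replacement", "adjustment", "dependent", "adoption",
             "communism", "activate", "angularity", "homologous", "effective",
             "probate", "rate", "cease", "controlling", "rolling",
             "generalizations", "argue", "arguing", "argued", "nanoparticles",
             "liposomal", "nanosuspension", "micelles", "doxorubicin",
             "studies", "study", "formalize", "sensitivity", "sensibility")
  stems <- c("caress", "poni", "ti", "caress", "cat", "feed", "agre",
             "plaster", "bled", "motor", "sing", "conflat", "troubl", "size",
             "hop", "tan", "fall", "hiss", "fizz", "fail", "file", "happi",
             "sky", "relat", "condit", "ration", "electr", "electr", "hope",
             "good", "reviv", "adjust", "defens", "irrit", "replac", "adjust",
             "depend", "adopt", "commun", "activ", "angular", "homolog",
             "effect", "probat", "rate", "ceas", "control", "roll", "gener",
             "argu", "argu", "argu", "nanoparticl", "liposom", "nanosuspens",
             "micel", "doxorubicin", "studi", "studi", "formal", "sensit",
             "sensibl")
  expect_equal(porter_stem(words), stems)
})

test_that("normalization is idempotent on its own output for a fixed vocabulary", {
  # fixed vocabulary whose stems are themselves fixed points of the pipeline
  words <- c("nanoparticles", "liposomal", "clinical", "trials", "treatment",
             "injection", "studies", "formulations", "magnetic", "delivery",
             "targeted", "tumors")
  once <- normalize_tokens(words)
  twice <- normalize_tokens(once)
  expect_equal(twice, once)
})

test_that("normalized tokens carry no uppercase letters or digits", {
  set.seed(77)
  texts <- replicate(50, paste(
    sample(c("Dose", "50mg", "NANO", "x2", "Trial-4", "alpha_7", "Under_score",
             "mixedCase", "UPPER", "123", "ab", "the"), 8, replace = TRUE),
    collapse = " "))
  for (tx in texts) {
    out <- normalize_tokens(tokenize(tx))
    expect_false(any(grepl("[A-Z0-9]", out)))
  }
})

test_that("n-gram extraction counts adjacent ordered pairs", {
  expect_equal(extract_ngrams(c("a3x", "b3x", "c3x"), n = 2),
               c(`a3x b3x` = 1L, `b3x c3x` = 1L))
  expect_equal(extract_ngrams("lonely", n = 2),
               stats::setNames(integer(0), character(0)))
  out <- extract_ngrams(c("nano", "gel", "nano", "gel"), n = 2)
  expect_equal(out[["nano gel"]], 2L)
  expect_equal(out[["gel nano"]], 1L)
  expect_error(extract_ngrams(c("a", "b"), n = 3), "must be 1 or 2")
})

test_that("bigram count equals tokens minus one when all bigrams are distinct", {
  toks <- paste0("tok", letters[1:9])
  bag <- extract_ngrams(toks, n = 2)
  expect_equal(sum(bag), length(toks) - 1L)
})

test_that("bigrams never cross field boundaries", {
  bag <- document_features("alpha beta\ngamma delta", n = 2)
  expect_setequal(names(bag), c("alpha beta", "gamma delta"))
  expect_false("beta gamma" %in% names(bag))
})

test_that("corpus feature statistics match hand counts", {
  one <- list(d1 = c(a = 2L, b = 1L))  # tokens [a, a, b]
  st <- corpus_feature_stats(one)
  expect_equal(st$per_document$total, 3)
  expect_equal(st$per_document$unique, 2L)
  expect_equal(unname(st$summary["total", ]), c(3, 3, 3, 0))

  two <- list(d1 = c(a = 1L), d2 = c(a = 1L, b = 1L))
  st2 <- corpus_feature_stats(two)
  expect_equal(st2$n_features, 2)
  expect_equal(st2$mean_document_frequency, 1.5)

  expect_error(corpus_feature_stats(list()), "empty")
})

test_that("document frequencies double-count identity holds on random bags", {
  for (seed in 1:5) {
    bags <- random_bags(12, 20, seed)
    st <- corpus_feature_stats(bags)
    df <- brute_force_df(bags)
    expect_equal(sum(df), sum(st$per_document$unique))
    expect_equal(st$mean_document_frequency, mean(df))
  }
})
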