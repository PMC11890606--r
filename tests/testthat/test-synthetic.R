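test_that("full-signal noiseless corpora contain exactly own-class markers", {
  spec <- synthetic_spec(n_docs = 60, signal_strength = 1, oov_rate = 0,
                         url_rate = 0, emoji_rate = 0, elongation_rate = 0,
                         seed = 3)
  corp <- generate_corpus(spec)
  markers <- attr(corp, "markers")
  for (i in seq_len(nrow(corp))) {
    toks <- strsplit(corp$text[i], " ")[[1]]
    own <- as.character(corp$label[i])
    other <- setdiff(names(markers), own)
    expect_gt(sum(toks %in% markers[[own]]), 0)
    expect_identical(sum(toks %in% unlist(markers[other])), 0L)
  }
})

test_that("generation is a pure function of the seed", {
  s <- synthetic_spec(n_docs = 50, seed = 11)
  expect_identical(generate_corpus(s), generate_corpus(s))
  s2 <- synthetic_spec(n_docs = 50, seed = 12)
  expect_false(identical(generate_corpus(s)$text, generate_corpus(s2)$text))
})

test_that("a trivial marker-lookup classifier recovers the class signal", {
  spec <- synthetic_spec(n_docs = 1000, n_classes = 2, signal_strength = 0.9,
                         seed = 21)
  corp <- generate_corpus(spec)
  markers <- attr(corp, "markers")
  clean <- normalize_corpus(corp)
  pred <- vapply(clean$text, function(tx) {
    toks <- strsplit(tx, " ")[[1]]
    hits <- vapply(markers, function(mk) sum(toks %in% mk), numeric(1))
    if (all(hits == 0)) 0L else as.integer(names(which.max(hits)))
  }, integer(1), USE.NAMES = FALSE)
  f1 <- precision_recall_f1(confusion(corp$label, pred, 1))$f1
  expect_gte(f1, 0.9)
})

test_that("class balance is within three sigma of uniform", {
  corp <- generate_corpus(synthetic_spec(n_docs = 1000, seed = 5))
  expect_lt(abs(mean(corp$label) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("the OOV injection rate is recovered empirically", {
  corp <- generate_corpus(synthetic_spec(n_docs = 5000, oov_rate = 0.1,
                                         seed = 6))
  expect_lt(abs(mean(attr(corp, "oov_flags")) - 0.1), 0.02)
  # injected novel strings really are out of a vocabulary built without them
  vocab <- build_vocab(normalize_corpus(corp[!attr(corp, "oov_flags"), ]))
  novel <- grepl("^zq[a-z]{8}$", names(vocab$word_to_id))
  expect_identical(sum(novel), 0L)
})

test_that("random corpora stream through the full pipeline without errors", {
  set.seed(33)
  for (i in 1:50) {
    spec <- synthetic_spec(
      n_docs = sample(20:60, 1), n_classes = sample(2:3, 1),
      vocab_size = sample(50:200, 1),
      doc_length = sort(sample(1:20, 2)),
      signal_strength = runif(1), oov_rate = runif(1, 0, 0.5),
      url_rate = runif(1, 0, 0.5), emoji_rate = runif(1, 0, 0.5),
      elongation_rate = runif(1, 0, 0.5), seed = i)
    corp <- generate_corpus(spec)
    clean <- normalize_corpus(corp)
    vocab <- build_vocab(clean)
    seqs <- encode_corpus(clean, vocab, max_len = 32)
    expect_length(seqs, nrow(corp))
    expect_true(all(vapply(seqs, function(s) length(s$ids) == 32L,
                           logical(1))))
  }
  expect_error(synthetic_spec(n_docs = 1, n_classes = 2), "n_docs")
})
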