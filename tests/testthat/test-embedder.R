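vocab_fix <- build_vocab(c("flu shot bad day", "sick season"))

test_that("tables are seed-deterministic with the documented shapes", {
  t1 <- init_tables(vocab_fix, max_len = 128, dim = 300, seed = 5)
  t2 <- init_tables(vocab_fix, max_len = 128, dim = 300, seed = 5)
  t3 <- init_tables(vocab_fix, max_len = 128, dim = 300, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$word_table, t3$word_table))
  expect_identical(nrow(t1$position_table), 128L)
  expect_identical(ncol(t1$word_table), 300L)
  expect_true(all(t1$word_table[1, ] == 0))         # padding row
  expect_error(init_tables(vocab_fix, dim = 0), "must be >= 1")
})

test_that("word vectors: lookup for known words, subunit sum for OOV", {
  tb <- init_tables(vocab_fix, max_len = 8, dim = 6, seed = 1)
  s <- encode("flu flus f", vocab_fix, max_len = 8)
  wid <- vocab_fix$word_to_id[["flu"]]
  expect_identical(word_vector(s, 1, tb), tb$word_table[wid + 1, ])
  units <- s$oov_map[["2"]]
  expect_gt(length(units), 1)
  expect_equal(word_vector(s, 2, tb),
               colSums(tb$subunit_table[units + 1, , drop = FALSE]))
  # single-subunit OOV equals that row exactly
  s1 <- encode("q", vocab_fix, max_len = 4)
  u1 <- s1$oov_map[["1"]]
  expect_length(u1, 1)
  expect_identical(word_vector(s1, 1, tb), tb$subunit_table[u1 + 1, ])
  expect_error(word_vector(s, 6, tb), "padding")
})

test_that("embedding concatenates word and positional halves end-to-end", {
  tb <- init_tables(vocab_fix, max_len = 8, dim = 5, seed = 2)
  s <- encode("flu shot flu", vocab_fix, max_len = 8)
  E <- embed_sequence(s, tb)
  expect_identical(dim(E), c(8L, 10L))
  # same word at positions 1 and 3: identical word half, different position half
  expect_identical(E[1, 1:5], E[3, 1:5])
  expect_false(isTRUE(all.equal(E[1, 6:10], E[3, 6:10])))
  expect_identical(E[1, 6:10], tb$position_table[1, ])
  # padding rows zero
  expect_true(all(E[4:8, ] == 0))
  # all-padding sequence gives the zero matrix
  s0 <- encode("", vocab_fix, max_len = 4)
  expect_true(all(embed_sequence(s0, tb) == 0))
})

test_that("position ablation duplicates the word half", {
  tb <- init_tables(vocab_fix, max_len = 4, dim = 5, seed = 2)
  s <- encode("flu shot", vocab_fix, max_len = 4)
  E <- embed_sequence(s, tb, use_position = FALSE)
  expect_identical(E[1, 1:5], E[1, 6:10])
})

test_that("word2vec text loading overwrites only listed, known words", {
  tb <- init_tables(vocab_fix, max_len = 4, dim = 3, seed = 3)
  f <- withr::local_tempfile()
  writeLines(c("2 3", "flu 1 2 3", "zebra 4 5 6"), f)
  tb2 <- load_word2vec(f, tb, vocab_fix)
  expect_identical(attr(tb2, "n_loaded"), 1L)
  expect_identical(tb2$word_table[vocab_fix$word_to_id[["flu"]] + 1, ],
                   c(1, 2, 3))
  wid_shot <- vocab_fix$word_to_id[["shot"]] + 1
  expect_identical(tb2$word_table[wid_shot, ], tb$word_table[wid_shot, ])
  writeLines(c("1 5", "flu 1 2 3 4 5"), f)
  expect_error(load_word2vec(f, tb, vocab_fix), "does not match")
})
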