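test_that("vocabulary construction respects the frequency threshold", {
  v1 <- build_vocab("a b a", min_count = 1)
  expect_setequal(names(v1$word_to_id), c("a", "b"))
  v2 <- build_vocab("a b a", min_count = 2)
  expect_setequal(names(v2$word_to_id), c("a"))
  v3 <- build_vocab(c("flu shot", "flu season"))
  expect_setequal(names(v3$word_to_id), c("flu", "shot", "season"))
  expect_true(all(c("f", "l", "u", "s", "h", "o", "t", "e", "a", "n", "flu")
                  %in% names(v3$subunit_to_id)))
  expect_error(build_vocab(character(0)), "empty corpus")
  # ids contiguous starting after the reserved 0/1
  expect_identical(sort(unname(v3$word_to_id)), 2:4)
})

test_that("vocabulary build is deterministic given corpus order", {
  corp <- c("flu shot season", "shot shot flu")
  expect_identical(build_vocab(corp), build_vocab(corp))
})

test_that("greedy longest-match segmentation covers every character", {
  v <- build_vocab(c("flu shot", "flu season"))
  ids <- segment_oov("flus", v)
  expect_identical(ids, unname(c(v$subunit_to_id["flu"], v$subunit_to_id["s"])))
  expect_identical(segment_oov("f", v), unname(v$subunit_to_id["f"]))
  expect_identical(segment_oov("qz", v), c(1L, 1L))   # unknown-subunit fallback
  expect_error(segment_oov("", v), "empty")
})

test_that("segmentation spans random words exactly once", {
  v <- build_vocab(c("flu shot bad sick day care", "season vaccine dose"))
  inv <- stats::setNames(names(v$subunit_to_id), v$subunit_to_id)
  set.seed(11)
  for (i in 1:100) {
    w <- paste(sample(c(letters, "_"), sample(1:12, 1), replace = TRUE),
               collapse = "")
    ids <- segment_oov(w, v)
    rebuilt <- paste(ifelse(ids == 1L, "?", inv[as.character(ids)]),
                     collapse = "")
    expect_identical(nchar(rebuilt), nchar(w))
    known <- strsplit(rebuilt, "")[[1]] != "?"
    expect_identical(strsplit(rebuilt, "")[[1]][known],
                     strsplit(w, "")[[1]][known])
  }
})

test_that("encoding pads, truncates and flags OOV positions", {
  v <- build_vocab(c("flu shot", "flu season"))
  s <- encode("flu shot", v, max_len = 4)
  expect_identical(s$ids, c(unname(v$word_to_id[c("flu", "shot")]), 0L, 0L))
  expect_identical(s$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_length(s$oov_map, 0)

  long <- paste(rep("flu", 200), collapse = " ")
  s2 <- encode(long, v, max_len = 128)
  expect_length(s2$ids, 128)
  expect_true(all(s2$mask))

  s3 <- encode("flus shot", v, max_len = 4)
  expect_identical(s3$ids[1], 1L)
  expect_identical(s3$oov_map[["1"]], segment_oov("flus", v))
})

test_that("in-vocabulary round trip reproduces the token sequence", {
  v <- build_vocab(c("flu shot season bad day"))
  txt <- "day flu season"
  s <- encode(txt, v, max_len = 8)
  expect_identical(decode_ids(s$ids[s$mask], v),
                   strsplit(txt, " ")[[1]])
})

test_that("vocabulary text serialization round-trips", {
  v <- build_vocab(c("flu shot", "flu season"), min_count = 1)
  path <- withr::local_tempfile()
  save_vocabulary(v, path)
  v2 <- load_vocabulary(path)
  expect_identical(v$word_to_id, v2$word_to_id)
  expect_identical(v$subunit_to_id, v2$subunit_to_id)
  expect_identical(v$min_count, v2$min_count)
})
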