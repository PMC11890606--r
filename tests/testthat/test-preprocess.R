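test_that("normalization applies the eight ordered steps", {
  expect_identical(normalize_text("Hello&amp;world"), "hello world")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("soooo   SICK!!! 102 fever"),
                   "soo sick number fever")
  expect_identical(normalize_text("Take 2 pills now &#33;"),
                   "take number pills now")
  expect_identical(normalize_text("@user check #flu http://t.co/x"),
                   "user check flu url")
})

test_that("URL replacement hits every maximal URL and nothing else", {
  expect_identical(replace_urls("see https://t.co/abc now"), "see URL now")
  expect_identical(replace_urls("no links here"), "no links here")
  expect_identical(replace_urls("http://a.b http://c.d"), "URL URL")
  expect_identical(replace_urls("www.example.com rocks"), "URL rocks")
})

test_that("emoji become underscore-joined short names from the shipped table", {
  expect_identical(replace_emojis("ok \U0001F44D"), "ok thumbs_up")
  expect_identical(replace_emojis("plain"), "plain")
  expect_identical(replace_emojis("\U0001F600\U0001F600"),
                   "grinning_face grinning_face")
  # variation-selector form maps to the same name
  expect_identical(replace_emojis("x ❤️"), "x red_heart")
  expect_identical(normalize_text("sick \U0001F912 today"),
                   "sick face_with_thermometer today")
})

test_that("normalization is idempotent and stays in the output alphabet", {
  set.seed(404)
  pieces <- c("He&amp;llo", "https://x.co/a", "\U0001F600", "soooo", "AA11",
              "café", "#tag", "@who", "a_b", "\t", "\n", "&#120;", "%",
              "你好", "x", " ")
  for (i in 1:200) {
    raw <- paste(sample(pieces, sample(1:8, 1), replace = TRUE),
                 collapse = sample(c(" ", ""), 1))
    once <- normalize_text(raw)
    expect_identical(normalize_text(once), once)
    expect_true(grepl("^[a-z0-9_ ]*$", once))
    expect_false(grepl("(.)\\1\\1", once))
    expect_false(grepl("  ", once))
  }
})

test_that("reserved tokens survive the pipeline", {
  expect_identical(normalize_text("url number"), "url number")
  expect_identical(normalize_text("URL and 42"), "url and number")
})

test_that("normalization is deterministic across calls", {
  x <- "RT @me: soooo sick \U0001F922 https://t.co/zz &amp; 102F!!!"
  expect_identical(normalize_text(x), normalize_text(x))
})

test_that("options change behaviour as documented", {
  expect_identical(
    normalize_text("MRI done", preprocess_options(caps_marker = TRUE)),
    "allcaps_mri done")
  expect_identical(
    normalize_text("ct 99", preprocess_options(replace_numbers = FALSE)),
    "ct 99")
  expect_identical(
    normalize_text("@doc hi", preprocess_options(mention_token = TRUE)),
    "mention hi")
  expect_identical(
    normalize_text("soooo", preprocess_options(elongation_cap = 3L)),
    "sooo")
})

test_that("corpus normalization preserves ids and labels", {
  docs <- data.frame(id = c("a", "b"), text = c("So SICK!", "fine"),
                     label = c(1L, 0L))
  out <- normalize_corpus(docs)
  expect_identical(out$id, docs$id)
  expect_identical(out$label, docs$label)
  expect_identical(out$text, c("so sick", "fine"))
})
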