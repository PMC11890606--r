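tf <- asNamespace("tweetformer")

tiny_cfg <- function(...) {
  base <- list(max_len = 8, embed_dim = 4, lstm_hidden = 3, n_heads = 2,
               d_h = 2, n_classes = 2, dropout = 0.3, batch_size = 4,
               seeds = list(init = 1, shuffle = 2, dropout = 3))
  do.call(model_config, utils::modifyList(base, list(...)))
}

tiny_corpus <- function(n = 24, seed = 9) {
  spec <- synthetic_spec(n_docs = n, vocab_size = 30, doc_length = c(3, 6),
                         signal_strength = 1, oov_rate = 0, url_rate = 0,
                         emoji_rate = 0, elongation_rate = 0, seed = seed)
  normalize_corpus(generate_corpus(spec))
}

test_that("configuration validates its invariants", {
  expect_error(model_config(task_mode = "binary", n_classes = 3),
               "n_classes = 2")
  expect_error(model_config(threshold = 0), "threshold")
  expect_error(model_config(warmup_fraction = 1), "warmup_fraction")
  cfg <- model_config()
  expect_identical(cfg$d_model, 300L)
  expect_identical(cfg$n_heads, 16L)
  expect_identical(cfg$epochs, 3L)
  expect_equal(cfg$learning_rate, 3e-5)
})

test_that("forward produces valid probabilities in every task mode", {
  docs <- tiny_corpus()
  vocab <- build_vocab(docs)
  m_bin <- model_init(vocab, tiny_cfg())
  set.seed(31)
  m_bin$dense_W[] <- rnorm(length(m_bin$dense_W))
  s <- encode(docs$text[1], vocab, 8)
  p <- model_forward(m_bin, s)
  expect_length(p, 1)
  expect_true(p > 0 && p < 1)

  m_mc <- model_init(vocab, tiny_cfg(n_classes = 3, task_mode = "multiclass"))
  set.seed(32)
  m_mc$dense_W[] <- rnorm(length(m_mc$dense_W))
  pm <- model_forward(m_mc, s)
  expect_length(pm, 3)
  expect_equal(sum(pm), 1, tolerance = 1e-12)
  expect_true(all(pm > 0))
})

test_that("ablation switches change the trainable-parameter bookkeeping", {
  docs <- tiny_corpus()
  vocab <- build_vocab(docs)
  m_full <- model_init(vocab, tiny_cfg())
  m_nop <- model_init(vocab, tiny_cfg(use_position_vector = FALSE))
  m_nol <- model_init(vocab, tiny_cfg(use_bilstm = FALSE))
  m_none <- model_init(vocab, tiny_cfg(use_position_vector = FALSE,
                                       use_bilstm = FALSE))
  # dropping the (frozen) position vector changes no trainable count;
  # dropping the BiLSTM removes exactly its weights and the fusion logits
  expect_identical(parameter_count(m_nop), parameter_count(m_full))
  lstm_n <- sum(vapply(
    list(m_full$ctx$layer1, m_full$ctx$layer2), function(ly) {
      sum(vapply(ly, function(d) length(d$Wx) + length(d$Wh) + length(d$b),
                 numeric(1)))
    }, numeric(1))) + length(m_full$ctx$fusion_logits)
  expect_identical(parameter_count(m_full) - parameter_count(m_nol), lstm_n)
  expect_identical(parameter_count(m_none), parameter_count(m_nol))
  # and the forward passes differ accordingly
  set.seed(77)
  W <- matrix(rnorm(length(m_full$dense_W)), nrow(m_full$dense_W))
  m_full$dense_W <- W
  m_nol$dense_W <- W
  s <- encode(docs$text[1], vocab, 8)
  expect_false(identical(model_forward(m_full, s), model_forward(m_nol, s)))
})

test_that("training is bit-reproducible given identical seeds", {
  docs <- tiny_corpus()
  vocab <- build_vocab(docs)
  seqs <- encode_corpus(docs, vocab, 8)
  cfg <- tiny_cfg(epochs = 2)
  m1 <- model_train(model_init(vocab, cfg), seqs)
  m2 <- model_train(model_init(vocab, cfg), seqs)
  attr(m1, "history") <- attr(m2, "history") <- NULL
  expect_identical(m1, m2)
  cfg3 <- tiny_cfg(epochs = 2, seeds = list(init = 1, shuffle = 5, dropout = 3))
  m3 <- model_train(model_init(vocab, cfg3), seqs)
  expect_false(identical(m1$dense_W, m3$dense_W))
})

test_that("training reduces the loss on a separable corpus", {
  docs <- tiny_corpus(n = 60, seed = 10)
  vocab <- build_vocab(docs)
  seqs <- encode_corpus(docs, vocab, 12)
  # a learning-sanity check, so use a learning rate that moves the weights
  cfg <- tiny_cfg(max_len = 12, epochs = 3, learning_rate = 3e-3)
  m <- model_train(model_init(vocab, cfg), seqs)
  h <- attr(m, "history")
  spe <- ceiling(length(seqs) / cfg$batch_size)
  expect_lt(mean(utils::tail(h$loss, spe)), mean(utils::head(h$loss, spe)))
  expect_true(all(is.finite(h$loss)))
})

test_that("the learning-rate schedule has the closed warmup/decay form", {
  T <- 75L
  lrs <- lr_schedule(T, 3e-5, 0.10)
  W <- ceiling(0.1 * T)
  expect_equal(lrs[W], 3e-5, tolerance = 1e-12)
  expect_equal(lrs[1], 3e-5 / W, tolerance = 1e-12)
  expect_equal(lrs[T], 0, tolerance = 1e-15)
  # conservation: sum of ratios equals the trapezoid area
  area <- (W + 1) / 2 + sum((T - (W + 1):T) / (T - W))
  expect_equal(sum(lrs / 3e-5), area, tolerance = 1e-9)
})

test_that("prediction applies the documented decision rules", {
  cfg_b <- tiny_cfg()
  expect_identical(tf$decide_labels(matrix(c(0.5, 0.49, 0.51), 3, 1), cfg_b),
                   c(1L, 0L, 1L))       # boundary probability counts positive
  cfg_m <- tiny_cfg(n_classes = 3, task_mode = "multiclass")
  probs <- rbind(c(0.2, 0.5, 0.3), c(0.4, 0.4, 0.2))
  expect_identical(tf$decide_labels(probs, cfg_m), c(1L, 0L))  # tie -> lower
  docs <- tiny_corpus()
  vocab <- build_vocab(docs)
  m <- model_init(vocab, cfg_b)
  expect_identical(model_predict(m, character(0)), integer(0))
  expect_length(model_predict(m, docs$text[1:3]), 3)
})

test_that("checkpoints round-trip bit-exactly", {
  docs <- tiny_corpus()
  vocab <- build_vocab(docs)
  seqs <- encode_corpus(docs, vocab, 8)
  m <- model_train(model_init(vocab, tiny_cfg(epochs = 1)), seqs)
  path <- withr::local_tempfile()
  save_model(m, path)
  m2 <- load_model(path)
  for (p in tf$all_param_paths(m)) {
    expect_identical(tf$get_leaf(m, p), tf$get_leaf(m2, p),
                     info = tf$leaf_name(p))
  }
  expect_identical(model_predict(m, docs$text), model_predict(m2, docs$text))
})
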