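# Independent reference implementations used as oracles.

# Straight-line per-token transcription of the additive-attention head:
# explicit loops, no vectorization shared with the implementation.
naive_head_oracle <- function(E, hp) {
  N <- nrow(E); dh <- length(hp$w_q)
  Q <- E %*% hp$Wq_proj; K <- E %*% hp$Wk_proj; V <- E %*% hp$Wv_proj
  a <- numeric(N)
  for (i in seq_len(N)) a[i] <- exp(sum(hp$w_q * Q[i, ]) / sqrt(dh))
  alpha <- a / sum(a)
  qg <- numeric(dh)
  for (i in seq_len(N)) qg <- qg + alpha[i] * Q[i, ]
  P <- matrix(0, N, dh)
  for (i in seq_len(N)) P[i, ] <- qg * K[i, ]
  b <- numeric(N)
  for (i in seq_len(N)) b[i] <- exp(sum(hp$w_k * P[i, ]) / sqrt(dh))
  beta <- b / sum(b)
  kg <- numeric(dh)
  for (i in seq_len(N)) kg <- kg + beta[i] * P[i, ]
  out <- matrix(0, N, dh)
  for (i in seq_len(N)) {
    u <- kg * V[i, ]
    out[i, ] <- as.numeric(t(hp$Wr) %*% u) + hp$br + Q[i, ]
  }
  list(out = out, alpha = alpha, beta = beta)
}

# Handwritten single-step LSTM recurrence over one sequence (N x d input),
# gate order [input | forget | cell | output].
lstm_reference <- function(X, Wx, Wh, b, reverse = FALSE) {
  N <- nrow(X); H <- nrow(Wh)
  idx <- if (reverse) N:1 else 1:N
  h <- numeric(H); c <- numeric(H)
  out <- matrix(0, N, H)
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in idx) {
    A <- as.numeric(X[t, ] %*% Wx) + as.numeric(h %*% Wh) + b
    gi <- sig(A[1:H]); gf <- sig(A[(H + 1):(2 * H)])
    gg <- tanh(A[(2 * H + 1):(3 * H)]); go <- sig(A[(3 * H + 1):(4 * H)])
    c <- gf * c + gi * gg
    h <- go * tanh(c)
    out[t, ] <- h
  }
  out
}

# Tiny model + batch used by gradient checks.
tiny_gradcheck_setup <- function(n_blocks = 1L) {
  tf <- asNamespace("tweetformer")
  vocab <- build_vocab(c("flu shot bad day", "sick soo bad", "ok fine day"))
  cfg <- model_config(max_len = 5, embed_dim = 4, lstm_hidden = 3,
                      n_heads = 2, d_h = 2, n_blocks = n_blocks, dropout = 0,
                      n_classes = 2, task_mode = "binary",
                      train_positions = TRUE,
                      seeds = list(init = 7, shuffle = 8, dropout = 9))
  model <- model_init(vocab, cfg)
  set.seed(99)
  model$dense_W <- matrix(rnorm(length(model$dense_W), sd = 0.5),
                          nrow(model$dense_W))
  model$dense_b <- rnorm(length(model$dense_b), sd = 0.1)
  docs <- data.frame(id = c("a", "b", "c"),
                     text = c("flu shot zzqq day", "sick soo",
                              "ok fine day bad day"),
                     label = c(1L, 1L, 0L), stringsAsFactors = FALSE)
  seqs <- encode_corpus(docs, vocab, cfg$max_len)
  y <- vapply(seqs, function(s) as.numeric(s$label), numeric(1))
  list(tf = tf, model = model, cfg = cfg, seqs = seqs, y = y)
}

# Maximum relative error between analytic and central-difference gradients
# for one parameter leaf.
leaf_grad_relerr <- function(setup, path, eps = 1e-6) {
  tf <- setup$tf
  loss_fn <- function(m) {
    fw <- tf$model_forward_batch(m, setup$seqs, training = FALSE)
    tf$model_loss(fw, setup$y, setup$cfg$task_mode)$loss
  }
  fw <- tf$model_forward_batch(setup$model, setup$seqs, training = FALSE)
  ls <- tf$model_loss(fw, setup$y, setup$cfg$task_mode)
  grads <- tf$model_backward_batch(setup$model, fw, ls$dlogits)
  nm <- tf$leaf_name(path)
  v <- tf$get_leaf(setup$model, path)
  g <- grads[[nm]]
  if (is.null(g)) return(NA_real_)
  num <- v * 0
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    num[i] <- (loss_fn(tf$set_leaf(setup$model, path, vp)) -
                 loss_fn(tf$set_leaf(setup$model, path, vm))) / (2 * eps)
  }
  if (nm == "tables.word_table") num[1L, ] <- 0
  max(abs(num - g) / pmax(abs(num), abs(g), 1e-6))
}
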