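tf <- asNamespace("tweetformer")

test_that("additive pooling matches its closed-form special cases", {
  set.seed(1)
  x1 <- matrix(rnorm(3), 1, 3)
  r <- additive_pool(x1, rnorm(3))
  expect_equal(r$weights, 1.0)
  expect_equal(r$pooled, as.numeric(x1))

  X <- matrix(rnorm(15), 5, 3)
  r0 <- additive_pool(X, c(0, 0, 0))
  expect_equal(r0$weights, rep(0.2, 5))
  expect_equal(r0$pooled, colMeans(X), tolerance = 1e-14)
})

test_that("additive pooling equals an explicit exp/sum loop", {
  set.seed(2)
  for (i in 1:20) {
    N <- sample(2:6, 1); dh <- sample(2:5, 1)
    X <- matrix(rnorm(N * dh), N, dh)
    w <- rnorm(dh)
    r <- additive_pool(X, w)
    e <- exp(as.numeric(X %*% w) / sqrt(dh))
    a_ref <- e / sum(e)
    p_ref <- colSums(X * a_ref)
    expect_equal(r$weights, a_ref, tolerance = 1e-10)
    expect_equal(r$pooled, p_ref, tolerance = 1e-10)
  }
})

test_that("pooling weights are shift-invariant, masked and sum to one", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  w <- rnorm(4)
  r <- additive_pool(X, w)
  expect_equal(sum(r$weights), 1, tolerance = 1e-12)
  # adding a constant to all logits: X -> X + c * w / |w|^2 * sqrt(dh)
  Xs <- X + matrix(5 * sqrt(4) * w / sum(w * w), 6, 4, byrow = TRUE)
  rs <- additive_pool(Xs, w)
  expect_equal(r$weights, rs$weights, tolerance = 1e-9)
  m <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  rm <- additive_pool(X, w, mask = m)
  expect_true(all(rm$weights[!m] == 0))
  expect_equal(sum(rm$weights), 1, tolerance = 1e-12)
  expect_error(additive_pool(X, w, mask = rep(FALSE, 6)), "empty sequence")
})

test_that("vectorized head equals the straight-line per-token transcription", {
  set.seed(4)
  worst <- 0
  for (i in 1:100) {
    N <- sample(2:8, 1); dh <- sample(2:4, 1); dm <- sample(3:6, 1)
    p <- tf$init_encoder_params(dm, n_heads = 1L, d_h = dh)
    hp <- tf$head_params(p, 1)
    E <- matrix(rnorm(N * dm), N, dm)
    ref <- naive_head_oracle(E, hp)
    out <- head_forward(E, hp)
    worst <- max(worst, max(abs(out - ref$out)))
    expect_equal(sum(ref$alpha), 1, tolerance = 1e-12)
    expect_equal(sum(ref$beta), 1, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-8)
})

test_that("all-zero input with zero bias maps to all-zero output", {
  set.seed(5)
  p <- tf$init_encoder_params(4, n_heads = 2L, d_h = 3)
  hp <- tf$head_params(p, 1)
  out <- head_forward(matrix(0, 5, 4), hp)
  expect_true(all(out == 0))
})

test_that("head output rows permute with the input rows", {
  set.seed(6)
  p <- tf$init_encoder_params(5, n_heads = 1L, d_h = 3)
  hp <- tf$head_params(p, 1)
  E <- matrix(rnorm(25), 5, 5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(head_forward(E, hp)[perm, ], head_forward(E[perm, ], hp),
               tolerance = 1e-12)
})

test_that("multi-head encoder concatenates heads and projects to d_model", {
  set.seed(7)
  p <- tf$init_encoder_params(6, n_heads = 4L, d_h = 3)
  E <- matrix(rnorm(42), 7, 6)
  out <- encoder_forward(E, p)
  expect_identical(dim(out), c(7L, 6L))
  # one head with an identity-like output projection reduces to head_forward
  p1 <- tf$init_encoder_params(3, n_heads = 1L, d_h = 3)
  p1$out_W <- diag(3)
  p1$out_b <- numeric(3)
  E3 <- matrix(rnorm(12), 4, 3)
  expect_equal(encoder_forward(E3, p1),
               head_forward(E3, tf$head_params(p1, 1)), tolerance = 1e-12)
})

test_that("operation count grows linearly in sequence length", {
  set.seed(8)
  p <- tf$init_encoder_params(300, n_heads = 16L, d_h = 32L)
  ratio <- count_encoder_ops(128, p) / count_encoder_ops(64, p)
  expect_lte(ratio, 2.2)
  expect_gte(ratio, 1.8)
})

test_that("EWMA weight generator follows its closed form", {
  expect_equal(ewma_update(c(0, 0), c(1, 1), 0.8), c(0.2, 0.2))
  b <- c(0.3, -0.5)
  expect_equal(ewma_update(b, b, 0.8), b)
  # constant gradient: buffer approaches g as 1 - rho^t
  g <- c(2, -1, 0.5)
  buf <- g * 0
  for (t in 1:50) {
    buf <- ewma_update(buf, g, 0.8)
    expect_equal(buf, g * (1 - 0.8^t), tolerance = 1e-12)
  }
  expect_error(ewma_update(c(1, 2), c(1, 2, 3), 0.8), "shape mismatch")
})
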