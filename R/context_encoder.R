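glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# One bidirectional layer's parameters: per-direction input weights
# (d_in x 4H), recurrent weights (H x 4H) and bias (4H). Forget-gate bias
# starts at 1 (standard; keeps the constant-error carousel open early).
init_bilstm_params <- function(d_in, H) {
  one_dir <- function() {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1
    list(Wx = glorot(d_in, 4L * H), Wh = glorot(H, 4L * H), b = b)
  }
  list(fwd = one_dir(), bwd = one_dir())
}

# Batched bidirectional pass; X is (B*L) x d_in in slot layout.
bilstm_batch <- function(X, params, B, L) {
  f <- .lstm_forward_cpp(X, params$fwd$Wx, params$fwd$Wh, params$fwd$b,
                         B, L, FALSE)
  r <- .lstm_forward_cpp(X, params$bwd$Wx, params$bwd$Wh, params$bwd$b,
                         B, L, TRUE)
  list(H = cbind(f$H, r$H), fwd = f, bwd = r, X = X, B = B, L = L)
}

bilstm_batch_backward <- function(dH, cache, params) {
  H <- ncol(cache$fwd$H)
  df <- .lstm_backward_cpp(dH[, seq_len(H), drop = FALSE], cache$X,
                           params$fwd$Wx, params$fwd$Wh,
                           cache$fwd$H, cache$fwd$C, cache$fwd$G,
                           cache$B, cache$L, FALSE)
  dr <- .lstm_backward_cpp(dH[, H + seq_len(H), drop = FALSE], cache$X,
                           params$bwd$Wx, params$bwd$Wh,
                           cache$bwd$H, cache$bwd$C, cache$bwd$G,
                           cache$B, cache$L, TRUE)
  list(dX = df$dX + dr$dX,
       grads = list(fwd = list(Wx = df$dWx, Wh = df$dWh, b = as.numeric(df$db)),
                    bwd = list(Wx = dr$dWx, Wh = dr$dWh, b = as.numeric(dr$db))))
}

#' Bidirectional LSTM layer over one sequence
#'
#' Runs the standard LSTM recurrence left-to-right and right-to-left with
#' zero initial states and concatenates the per-position outputs, giving
#' width `2H` (e.g. 300 = 150 forward + 150 backward). The recurrence
#' visits every position; masked positions carry zero input vectors.
#'
#' @param inputs numeric matrix `N x d_in`.
#' @param params one layer's parameters: `list(fwd, bwd)` each with `Wx`
#'   (`d_in x 4H`), `Wh` (`H x 4H`), `b` (`4H`); see the package's model
#'   constructor.
#' @param mask optional logical vector length `N` (`TRUE` = real token);
#'   masked positions have their input zeroed.
#' @return numeric matrix `N x 2H`.
#' @export
bilstm_layer <- function(inputs, params, mask = NULL) {
  if (!all(is.finite(inputs))) stop("non-finite inputs to LSTM layer")
  if (!is.null(mask)) inputs[!mask, ] <- 0
  bilstm_batch(inputs, params, B = 1L, L = nrow(inputs))$H
}

# Fusion weights: softmax over the three learned logits.
fusion_weights <- function(fusion_logits) {
  z <- fusion_logits - max(fusion_logits)
  e <- exp(z)
  e / sum(e)
}

init_context_params <- function(d_embed, H, dropout_rate = 0.3) {
  d_model <- 2L * H
  list(in_proj_W = glorot(d_embed, d_model), in_proj_b = numeric(d_model),
       layer1 = init_bilstm_params(d_embed, H),
       layer2 = init_bilstm_params(d_model, H),
       fusion_logits = numeric(3L),
       dropout_rate = dropout_rate)
}

# Full context pass, batched. training=TRUE applies inverted dropout to the
# two intermediate sequences (seeded by the caller's RNG state).
context_encode_batch <- function(X, params, B, L, training = FALSE) {
  h0 <- sweep(X %*% params$in_proj_W, 2L, params$in_proj_b, "+")
  c1 <- bilstm_batch(X, params$layer1, B, L)
  h1 <- c1$H
  m1 <- NULL
  if (training && params$dropout_rate > 0) {
    m1 <- matrix(stats::rbinom(length(h1), 1L, 1 - params$dropout_rate) /
                   (1 - params$dropout_rate), nrow(h1), ncol(h1))
    h1 <- h1 * m1
  }
  c2 <- bilstm_batch(h1, params$layer2, B, L)
  h2 <- c2$H
  m2 <- NULL
  if (training && params$dropout_rate > 0) {
    m2 <- matrix(stats::rbinom(length(h2), 1L, 1 - params$dropout_rate) /
                   (1 - params$dropout_rate), nrow(h2), ncol(h2))
    h2 <- h2 * m2
  }
  w <- fusion_weights(params$fusion_logits)
  out <- w[1] * h0 + w[2] * h1 + w[3] * h2
  list(out = out, h0 = h0, h1 = h1, h2 = h2, m1 = m1, m2 = m2,
       c1 = c1, c2 = c2, w = w, X = X)
}

context_encode_batch_backward <- function(dout, cache, params) {
  w <- cache$w
  dw <- c(sum(dout * cache$h0), sum(dout * cache$h1), sum(dout * cache$h2))
  dlogits <- w * (dw - sum(w * dw))        # softmax backward
  dh0 <- w[1] * dout
  dh1 <- w[2] * dout
  dh2 <- w[3] * dout
  if (!is.null(cache$m2)) dh2 <- dh2 * cache$m2
  b2 <- bilstm_batch_backward(dh2, cache$c2, params$layer2)
  dh1 <- dh1 + b2$dX
  if (!is.null(cache$m1)) dh1 <- dh1 * cache$m1
  b1 <- bilstm_batch_backward(dh1, cache$c1, params$layer1)
  dX <- b1$dX + tcrossprod(dh0, params$in_proj_W)
  grads <- list(in_proj_W = crossprod(cache$X, dh0),
                in_proj_b = colSums(dh0),
                layer1 = b1$grads, layer2 = b2$grads,
                fusion_logits = dlogits)
  list(dX = dX, grads = grads)
}

#' Context-encode an embedded sequence
#'
#' Output is the learned softmax-weighted sum of three
#' same-width sequences: the linearly projected input embeddings, the
#' first bidirectional LSTM layer's outputs, and the second layer's
#' outputs. Dropout is applied to the two LSTM sequences during training
#' only, so evaluation-mode calls are deterministic.
#'
#' @param embedded numeric matrix `N x d_embed` from [embed_sequence()].
#' @param params context-encoder parameters (see the model constructor);
#'   contains the `d_embed -> 2H` input projection, two bidirectional
#'   layers and the three fusion logits.
#' @param mask optional logical vector length `N`.
#' @param training apply dropout (default `FALSE`).
#' @return numeric matrix `N x 2H`.
#' @export
context_encode <- function(embedded, params, mask = NULL, training = FALSE) {
  if (!is.null(mask)) embedded[!mask, ] <- 0
  context_encode_batch(embedded, params, B = 1L, L = nrow(embedded),
                       training = training)$out
}
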