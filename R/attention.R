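#' Exponentially weighted moving average of a gradient
#'
#' The weight-generator rule used for the attention scoring vectors: the
#' optimizer consumes `rho * buffer + (1 - rho) * grad` in place of the raw
#' gradient when updating the global-query and global-key scoring vectors
#' (`rho = 0.8` by default). Under a constant gradient `g` the buffer
#' converges to `g` geometrically with ratio `rho`.
#'
#' @param buffer current EWMA buffer.
#' @param grad new raw gradient, same shape.
#' @param rho smoothing coefficient in `[0, 1)`.
#' @return the updated buffer.
#' @examples
#' ewma_update(c(0, 0), c(1, 1), 0.8)   # first step: (1 - rho) * grad
#' @export
ewma_update <- function(buffer, grad, rho = 0.8) {
  if (length(buffer) != length(grad)) stop("buffer/grad shape mismatch")
  stopifnot(rho >= 0, rho < 1)
  rho * buffer + (1 - rho) * grad
}

new_op_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$madds <- 0
  e
}
cnt <- function(counter, n) {
  if (!is.null(counter)) counter$madds <- counter$madds + n
  invisible(NULL)
}

# Row-wise masked softmax over an B x L logit matrix; masked entries get
# zero weight. Errors if any row is fully masked.
masked_softmax <- function(logits, mask_m) {
  logits[!mask_m] <- -Inf
  if (any(rowSums(mask_m) == 0L)) stop("empty sequence: all positions masked")
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e[!mask_m] <- 0
  e / rowSums(e)
}

#' Additive-attention pooling
#'
#' Scores each row of `X` against a learned vector `w`
#' (`logit_i = w %*% x_i / sqrt(d_h)`), softmax-normalizes the scores over
#' unmasked positions, and returns the attention-weighted sum of rows —
#' the O(N) summarization used for both the global query and the global
#' key.
#'
#' @param X numeric matrix `N x d_h`.
#' @param w numeric scoring vector of length `d_h`.
#' @param mask optional logical vector length `N`; at least one `TRUE`.
#' @return list with `weights` (length `N`, a probability vector over
#'   unmasked positions) and `pooled` (length `d_h`).
#' @export
additive_pool <- function(X, w, mask = NULL) {
  N <- nrow(X)
  if (is.null(mask)) mask <- rep(TRUE, N)
  if (!any(mask)) stop("empty sequence: all positions masked")
  r <- pool_batch(X, w, matrix(mask, 1L, N), B = 1L, L = N)
  list(weights = as.numeric(r$alpha), pooled = as.numeric(r$pooled))
}

# Batched pooling. X: (B*L) x d_h in slot layout; mask_m: B x L.
pool_batch <- function(X, w, mask_m, B, L, counter = NULL) {
  dh <- ncol(X)
  logits <- matrix((X %*% w) / sqrt(dh), B, L)
  cnt(counter, length(X))
  alpha <- masked_softmax(logits, mask_m)
  cnt(counter, 3L * B * L)
  af <- as.vector(alpha)
  pooled <- rowsum(X * af, group = rep(seq_len(B), L), reorder = TRUE)
  rownames(pooled) <- NULL
  cnt(counter, 2L * length(X))
  list(alpha = alpha, pooled = pooled, logits = logits)
}

pool_batch_backward <- function(dpooled, dalpha_extra, r, X, w, mask_m, B, L) {
  dh <- ncol(X)
  grp <- rep(seq_len(B), L)
  af <- as.vector(r$alpha)
  dX <- dpooled[grp, , drop = FALSE] * af
  dalpha <- matrix(rowSums(dpooled[grp, , drop = FALSE] * X), B, L)
  if (!is.null(dalpha_extra)) dalpha <- dalpha + dalpha_extra
  dlog <- r$alpha * (dalpha - rowSums(r$alpha * dalpha))
  dlf <- as.vector(dlog) / sqrt(dh)
  dX <- dX + tcrossprod(dlf, w)
  dw <- colSums(X * dlf)
  list(dX = dX, dw = dw)
}

# Stacked encoder parameters: projections for all heads side by side.
init_encoder_params <- function(d_model, n_heads = 16L, d_h = 32L) {
  dc <- n_heads * d_h
  Wr <- array(0, c(d_h, d_h, n_heads))
  for (h in seq_len(n_heads)) Wr[, , h] <- glorot(d_h, d_h)
  list(Wq = glorot(d_model, dc), Wk = glorot(d_model, dc),
       Wv = glorot(d_model, dc),
       wq_vec = matrix(stats::rnorm(d_h * n_heads, sd = 1 / sqrt(d_h)), d_h, n_heads),
       wk_vec = matrix(stats::rnorm(d_h * n_heads, sd = 1 / sqrt(d_h)), d_h, n_heads),
       Wr = Wr, br = matrix(0, d_h, n_heads),
       out_W = glorot(dc, d_model), out_b = numeric(d_model),
       n_heads = as.integer(n_heads), d_h = as.integer(d_h),
       d_model = as.integer(d_model))
}

# Per-head parameter view (the "attention head" object of the public API).
head_params <- function(params, h) {
  blk <- (h - 1L) * params$d_h + seq_len(params$d_h)
  list(Wq_proj = params$Wq[, blk, drop = FALSE],
       Wk_proj = params$Wk[, blk, drop = FALSE],
       Wv_proj = params$Wv[, blk, drop = FALSE],
       w_q = params$wq_vec[, h], w_k = params$wk_vec[, h],
       Wr = params$Wr[, , h], br = params$br[, h])
}

#' Single additive-attention head
#'
#' Projects the input sequence to per-token query, key and value vectors,
#' pools the queries into one global query, forms the context-aware key
#' matrix by elementwise product of the global query with each key, pools
#' that into a global key, modulates the values by the global key,
#' transforms each result linearly, and adds the residual query:
#' `out_i = Wr (k_glob * v_i) + br + q_i`.
#'
#' @param E numeric matrix `N x d_model`.
#' @param params a per-head parameter list with `Wq_proj`, `Wk_proj`,
#'   `Wv_proj` (`d_model x d_h`), scoring vectors `w_q`, `w_k`, transform
#'   `Wr` (`d_h x d_h`) and bias `br`.
#' @param mask optional logical vector length `N`.
#' @return numeric matrix `N x d_h`.
#' @export
head_forward <- function(E, params, mask = NULL) {
  if (!all(is.finite(E))) stop("non-finite attention input")
  N <- nrow(E)
  if (is.null(mask)) mask <- rep(TRUE, N)
  mask_m <- matrix(mask, 1L, N)
  Q <- E %*% params$Wq_proj
  K <- E %*% params$Wk_proj
  V <- E %*% params$Wv_proj
  pq <- pool_batch(Q, params$w_q, mask_m, 1L, N)
  P <- K * pq$pooled[rep(1L, N), ]
  pk <- pool_batch(P, params$w_k, mask_m, 1L, N)
  U <- V * pk$pooled[rep(1L, N), ]
  R <- U %*% params$Wr + matrix(params$br, N, length(params$br), byrow = TRUE)
  R + Q
}

# Batched multi-head encoder forward with cache for backward.
# E: (B*L) x d_model slot layout, mask_m: B x L.
encoder_batch <- function(E, params, mask_m, B, L, counter = NULL) {
  nh <- params$n_heads; dh <- params$d_h
  grp <- rep(seq_len(B), L)
  Q <- E %*% params$Wq; K <- E %*% params$Wk; V <- E %*% params$Wv
  cnt(counter, 3 * nrow(E) * ncol(E) * ncol(Q))
  Concat <- matrix(0, nrow(E), nh * dh)
  heads <- vector("list", nh)
  for (h in seq_len(nh)) {
    blk <- (h - 1L) * dh + seq_len(dh)
    Qh <- Q[, blk, drop = FALSE]
    Kh <- K[, blk, drop = FALSE]
    Vh <- V[, blk, drop = FALSE]
    pq <- pool_batch(Qh, params$wq_vec[, h], mask_m, B, L, counter)
    P <- Kh * pq$pooled[grp, , drop = FALSE]
    cnt(counter, length(P))
    pk <- pool_batch(P, params$wk_vec[, h], mask_m, B, L, counter)
    U <- Vh * pk$pooled[grp, , drop = FALSE]
    cnt(counter, length(U))
    R <- U %*% params$Wr[, , h]
    R <- sweep(R, 2L, params$br[, h], "+")
    cnt(counter, nrow(U) * dh * dh)
    Concat[, blk] <- R + Qh
    heads[[h]] <- list(pq = pq, pk = pk, P = P, U = U)
  }
  out <- sweep(Concat %*% params$out_W, 2L, params$out_b, "+")
  cnt(counter, nrow(Concat) * ncol(Concat) * ncol(out))
  list(out = out, Q = Q, K = K, V = V, Concat = Concat, heads = heads,
       E = E, mask_m = mask_m, B = B, L = L)
}

encoder_batch_backward <- function(dout, cache, params) {
  nh <- params$n_heads; dh <- params$d_h
  B <- cache$B; L <- cache$L
  grp <- rep(seq_len(B), L)
  dConcat <- tcrossprod(dout, params$out_W)
  g <- list(out_W = crossprod(cache$Concat, dout), out_b = colSums(dout),
            Wr = array(0, dim(params$Wr)), br = matrix(0, dh, nh),
            wq_vec = matrix(0, dh, nh), wk_vec = matrix(0, dh, nh))
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(nh)) {
    blk <- (h - 1L) * dh + seq_len(dh)
    hd <- cache$heads[[h]]
    Qh <- cache$Q[, blk, drop = FALSE]
    Kh <- cache$K[, blk, drop = FALSE]
    Vh <- cache$V[, blk, drop = FALSE]
    dH <- dConcat[, blk, drop = FALSE]
    dQh <- dH                                     # residual branch
    dR <- dH
    dU <- tcrossprod(dR, params$Wr[, , h])
    g$Wr[, , h] <- crossprod(hd$U, dR)
    g$br[, h] <- colSums(dR)
    dkg <- rowsum(dU * Vh, grp)
    dV[, blk] <- dU * hd$pk$pooled[grp, , drop = FALSE]
    pb <- pool_batch_backward(dkg, NULL, hd$pk, hd$P, params$wk_vec[, h],
                              cache$mask_m, B, L)
    g$wk_vec[, h] <- pb$dw
    dP <- pb$dX
    dK[, blk] <- dP * hd$pq$pooled[grp, , drop = FALSE]
    dqg <- rowsum(dP * Kh, grp)
    pa <- pool_batch_backward(dqg, NULL, hd$pq, Qh, params$wq_vec[, h],
                              cache$mask_m, B, L)
    g$wq_vec[, h] <- pa$dw
    dQ[, blk] <- dQh + pa$dX
  }
  dE <- tcrossprod(dQ, params$Wq) + tcrossprod(dK, params$Wk) +
    tcrossprod(dV, params$Wv)
  g$Wq <- crossprod(cache$E, dQ)
  g$Wk <- crossprod(cache$E, dK)
  g$Wv <- crossprod(cache$E, dV)
  list(dE = dE, grads = g)
}

#' Multi-head additive-attention encoder
#'
#' Runs [head_forward()] for every head, concatenates the per-head outputs
#' and applies the output projection back to `d_model`. Every intermediate
#' is `O(N)` in the sequence length — no pairwise `N x N` interaction
#' matrix is ever materialized.
#'
#' @param E numeric matrix `N x d_model`.
#' @param params encoder parameters (16 heads by default; see the model
#'   constructor).
#' @param mask optional logical vector length `N`.
#' @return numeric matrix `N x d_model`.
#' @export
encoder_forward <- function(E, params, mask = NULL) {
  if (!all(is.finite(E))) stop("non-finite attention input")
  N <- nrow(E)
  if (is.null(mask)) mask <- rep(TRUE, N)
  encoder_batch(E, params, matrix(mask, 1L, N), B = 1L, L = N)$out
}

#' Count multiply-accumulate operations of an encoder pass
#'
#' Runs [encoder_forward()] on a random input of length `N` with an
#' instrumented counter that accumulates the size of every matrix product
#' and elementwise operation actually executed, and returns the total.
#' Used to demonstrate linear scaling in `N`.
#'
#' @param N sequence length.
#' @param params encoder parameters.
#' @param d_model model width (defaults to `params$d_model`).
#' @return total multiply-accumulate count (numeric scalar).
#' @export
count_encoder_ops <- function(N, params, d_model = params$d_model) {
  counter <- new_op_counter()
  E <- matrix(0, N, d_model)
  invisible(encoder_batch(E, params, matrix(TRUE, 1L, N), 1L, N,
                          counter = counter))
  counter$madds
}
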