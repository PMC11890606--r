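#' Model configuration
#'
#' All architectural and training hyperparameters with the defaults used
#' throughout: 3 training epochs at learning rate 3e-5 with the
#' adaptive-moment optimizer, linear warmup over the first 10% of steps
#' then linear decay to zero, batch size 64, maximum sequence length 128,
#' decision threshold 0.5, two-layer BiLSTM with 150 units per direction
#' (so the model width is 300), dropout 0.3 on the LSTM outputs, 16
#' attention heads of width 32, and gradient smoothing coefficient
#' `rho = 0.8` for the attention scoring vectors.
#'
#' @param max_len maximum sequence length.
#' @param embed_dim word-vector width (the position-augmented input is
#'   `2 * embed_dim` wide).
#' @param lstm_hidden LSTM units per direction; the model width is
#'   `2 * lstm_hidden`.
#' @param n_heads number of attention heads.
#' @param d_h per-head width.
#' @param n_blocks number of stacked attention encoder blocks.
#' @param dropout dropout rate on the two LSTM output sequences.
#' @param n_classes number of classes.
#' @param task_mode `"binary"`, `"multiclass"` or `"multilabel"`.
#' @param threshold decision threshold for sigmoid outputs; probability
#'   exactly at the threshold counts as positive.
#' @param epochs,learning_rate,batch_size,warmup_fraction training recipe.
#' @param rho EWMA coefficient for the attention scoring-vector gradients.
#' @param seeds list with integer `init`, `shuffle`, `dropout`.
#' @param use_position_vector ablation switch: `FALSE` duplicates the word
#'   vector in place of the positional vector.
#' @param use_bilstm ablation switch: `FALSE` feeds linearly projected
#'   embeddings straight to attention.
#' @param train_positions train the positional table (default frozen).
#' @param min_count vocabulary frequency threshold.
#' @return list of class `tf_model_config`.
#' @export
model_config <- function(max_len = 128L, embed_dim = 300L, lstm_hidden = 150L,
                         n_heads = 16L, d_h = 32L, n_blocks = 1L,
                         dropout = 0.3, n_classes = 2L, task_mode = "binary",
                         threshold = 0.5, epochs = 3L, learning_rate = 3e-5,
                         batch_size = 64L, warmup_fraction = 0.10, rho = 0.8,
                         seeds = list(init = 1L, shuffle = 2L, dropout = 3L),
                         use_position_vector = TRUE, use_bilstm = TRUE,
                         train_positions = FALSE, min_count = 1L) {
  task_mode <- match.arg(task_mode, c("binary", "multiclass", "multilabel"))
  stopifnot(max_len >= 1, embed_dim >= 1, lstm_hidden >= 1, n_heads >= 1,
            d_h >= 1, n_blocks >= 1, dropout >= 0, dropout < 1,
            n_classes >= 2, threshold > 0, threshold < 1, epochs >= 1,
            learning_rate > 0, batch_size >= 1,
            warmup_fraction >= 0, warmup_fraction < 1, rho >= 0, rho < 1)
  if (task_mode == "binary" && n_classes != 2L)
    stop("binary task_mode requires n_classes = 2")
  structure(list(max_len = as.integer(max_len), embed_dim = as.integer(embed_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 d_model = 2L * as.integer(lstm_hidden),
                 n_heads = as.integer(n_heads), d_h = as.integer(d_h),
                 n_blocks = as.integer(n_blocks), dropout = dropout,
                 n_classes = as.integer(n_classes), task_mode = task_mode,
                 threshold = threshold, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 warmup_fraction = warmup_fraction, rho = rho,
                 seeds = lapply(seeds, as.integer),
                 use_position_vector = isTRUE(use_position_vector),
                 use_bilstm = isTRUE(use_bilstm),
                 train_positions = isTRUE(train_positions),
                 min_count = as.integer(min_count)),
            class = "tf_model_config")
}

#' Initialize a model
#'
#' Embedding tables follow [init_tables()]; dense projections use
#' Glorot-uniform initialization; the classification head starts at zero
#' so initial class probabilities are uniform and early training is driven
#' by the label signal alone.
#'
#' @param vocab a [build_vocab()] result.
#' @param config a [model_config()].
#' @return list of class `tf_model`.
#' @export
model_init <- function(vocab, config = model_config()) {
  tables <- init_tables(vocab, max_len = config$max_len,
                        dim = config$embed_dim, seed = config$seeds$init,
                        train_positions = config$train_positions)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seeds$init + 1L)
  ctx <- init_context_params(2L * config$embed_dim, config$lstm_hidden,
                             dropout_rate = config$dropout)
  enc <- lapply(seq_len(config$n_blocks), function(k) {
    init_encoder_params(config$d_model, config$n_heads, config$d_h)
  })
  C_out <- if (config$task_mode == "binary") 1L else config$n_classes
  model <- structure(list(config = config, vocab = vocab, tables = tables,
                          ctx = ctx, enc = enc,
                          dense_W = matrix(0, config$d_model, C_out),
                          dense_b = numeric(C_out)),
                     class = "tf_model")
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  model
}

#' @export
print.tf_model <- function(x, ...) {
  cat(sprintf(paste0("<tf_model> %s, %d classes, d_model=%d, %d heads x d_h=%d, ",
                     "%d block(s), %s trainable parameters\n"),
              x$config$task_mode, x$config$n_classes, x$config$d_model,
              x$config$n_heads, x$config$d_h, x$config$n_blocks,
              format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

# --- trainable-parameter registry -----------------------------------------

leaf_paths <- function(model) {
  cfg <- model$config
  p <- list(c("tables", "word_table"), c("tables", "subunit_table"))
  if (cfg$train_positions && cfg$use_position_vector)
    p <- c(p, list(c("tables", "position_table")))
  p <- c(p, list(c("ctx", "in_proj_W"), c("ctx", "in_proj_b")))
  if (cfg$use_bilstm) {
    for (ly in c("layer1", "layer2"))
      for (dr in c("fwd", "bwd"))
        for (m in c("Wx", "Wh", "b"))
          p <- c(p, list(c("ctx", ly, dr, m)))
    p <- c(p, list(c("ctx", "fusion_logits")))
  }
  for (k in seq_along(model$enc))
    for (m in c("Wq", "Wk", "Wv", "wq_vec", "wk_vec", "Wr", "br",
                "out_W", "out_b"))
      p <- c(p, list(c("enc", as.character(k), m)))
  c(p, list("dense_W", "dense_b"))
}

get_leaf <- function(obj, path) {
  for (k in path) obj <- if (grepl("^[0-9]+$", k)) obj[[as.integer(k)]] else obj[[k]]
  obj
}

set_leaf <- function(obj, path, value) {
  k <- path[1]
  key <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
  if (length(path) == 1L) obj[[key]] <- value
  else obj[[key]] <- set_leaf(obj[[key]], path[-1], value)
  obj
}

leaf_name <- function(path) paste(path, collapse = ".")

#' Count trainable parameters of a model variant
#'
#' Respects the ablation switches: the positional table is counted only
#' when trainable, and the BiLSTM stack and fusion logits only when
#' `use_bilstm` is on.
#'
#' @param model a [model_init()] result.
#' @return integer count.
#' @export
parameter_count <- function(model) {
  sum(vapply(leaf_paths(model), function(p) length(get_leaf(model, p)),
             numeric(1)))
}

# --- forward / backward ----------------------------------------------------

model_forward_batch <- function(model, seqs, training = FALSE,
                                counter = NULL) {
  cfg <- model$config
  B <- length(seqs)
  L <- max(1L, min(cfg$max_len,
                   max(vapply(seqs, function(s) s$n_tokens, integer(1)))))
  emb <- embed_batch(seqs, model$tables, L, cfg$use_position_vector)
  grp <- rep(seq_len(B), L)
  mask_m <- matrix(emb$mask, B, L)
  if (cfg$use_bilstm) {
    ctx <- context_encode_batch(emb$X, model$ctx, B, L, training = training)
    H <- ctx$out
  } else {
    ctx <- list(X = emb$X)
    H <- sweep(emb$X %*% model$ctx$in_proj_W, 2L, model$ctx$in_proj_b, "+")
  }
  enc_caches <- vector("list", length(model$enc))
  E <- H
  for (k in seq_along(model$enc)) {
    enc_caches[[k]] <- encoder_batch(E, model$enc[[k]], mask_m, B, L,
                                     counter = counter)
    E <- enc_caches[[k]]$out
  }
  n_tok <- pmax(1L, rowSums(mask_m))
  pooled <- rowsum(E * emb$mask, grp) / n_tok
  logits <- sweep(pooled %*% model$dense_W, 2L, model$dense_b, "+")
  probs <- switch(cfg$task_mode,
    binary = 1 / (1 + exp(-logits)),
    multilabel = 1 / (1 + exp(-logits)),
    multiclass = {
      z <- logits - apply(logits, 1L, max)
      ez <- exp(z)
      ez / rowSums(ez)
    })
  list(probs = probs, logits = logits, pooled = pooled, E = E,
       enc_caches = enc_caches, ctx = ctx, emb = emb, mask_m = mask_m,
       grp = grp, n_tok = n_tok, B = B, L = L)
}

# Mean cross-entropy loss and gradient w.r.t. logits.
model_loss <- function(fw, labels, task_mode) {
  B <- fw$B
  z <- fw$logits
  if (task_mode == "binary") {
    y <- as.numeric(labels)
    zl <- as.numeric(z)
    loss <- mean(pmax(zl, 0) - zl * y + log1p(exp(-abs(zl))))
    dlogits <- matrix((fw$probs - y) / B, B, 1L)
  } else if (task_mode == "multilabel") {
    Y <- labels                                  # B x C 0/1 matrix
    loss <- mean(rowSums(pmax(z, 0) - z * Y + log1p(exp(-abs(z)))))
    dlogits <- (fw$probs - Y) / B
  } else {
    y <- as.integer(labels) + 1L                 # class indices 0-based
    idx <- cbind(seq_len(B), y)
    loss <- -mean(log(pmax(fw$probs[idx], 1e-300)))
    dlogits <- fw$probs / B
    dlogits[idx] <- dlogits[idx] - 1 / B
  }
  list(loss = loss, dlogits = dlogits)
}

model_backward_batch <- function(model, fw, dlogits, sparse_tables = FALSE) {
  cfg <- model$config
  grads <- list()
  grads[["dense_W"]] <- crossprod(fw$pooled, dlogits)
  grads[["dense_b"]] <- colSums(dlogits)
  dpooled <- tcrossprod(dlogits, model$dense_W)
  dE <- dpooled[fw$grp, , drop = FALSE] * (fw$emb$mask / fw$n_tok[fw$grp])
  for (k in rev(seq_along(model$enc))) {
    eb <- encoder_batch_backward(dE, fw$enc_caches[[k]], model$enc[[k]])
    dE <- eb$dE
    for (m in names(eb$grads))
      grads[[leaf_name(c("enc", as.character(k), m))]] <- eb$grads[[m]]
  }
  if (cfg$use_bilstm) {
    cb <- context_encode_batch_backward(dE, fw$ctx, model$ctx)
    dX <- cb$dX
    g <- cb$grads
    grads[["ctx.in_proj_W"]] <- g$in_proj_W
    grads[["ctx.in_proj_b"]] <- g$in_proj_b
    grads[["ctx.fusion_logits"]] <- g$fusion_logits
    for (ly in c("layer1", "layer2"))
      for (dr in c("fwd", "bwd"))
        for (m in c("Wx", "Wh", "b"))
          grads[[leaf_name(c("ctx", ly, dr, m))]] <- g[[ly]][[dr]][[m]]
  } else {
    dX <- tcrossprod(dE, model$ctx$in_proj_W)
    grads[["ctx.in_proj_W"]] <- crossprod(fw$ctx$X, dE)
    grads[["ctx.in_proj_b"]] <- colSums(dE)
  }
  et <- embed_batch_backward(dX, fw$emb, model$tables,
                             cfg$use_position_vector,
                             dense = !sparse_tables)
  grads[["tables.word_table"]] <- et$word
  grads[["tables.subunit_table"]] <- et$subunit
  if (cfg$train_positions && cfg$use_position_vector)
    grads[["tables.position_table"]] <- et$position
  grads
}

#' Forward pass for one encoded document
#'
#' Embeds the sequence, context-encodes it, applies the attention encoder,
#' mean-pools the unmasked positions and applies the dense classification
#' head: sigmoid for binary/multilabel tasks, softmax for multiclass.
#'
#' @param model a `tf_model`.
#' @param seq a [encode()] result.
#' @return numeric vector of class probabilities (length 1 for binary).
#' @export
model_forward <- function(model, seq) {
  fw <- model_forward_batch(model, list(seq), training = FALSE)
  p <- as.numeric(fw$probs[1L, ])
  if (model$config$task_mode == "multiclass")
    names(p) <- as.character(seq_len(model$config$n_classes) - 1L)
  p
}

# --- optimizer -------------------------------------------------------------

#' Learning-rate schedule with linear warmup and linear decay
#'
#' `lr_t = lr * t / W` for the first `W = ceiling(warmup_fraction * T)`
#' steps, then decays linearly to zero at step `T`.
#'
#' @param total_steps total optimizer steps `T`.
#' @param learning_rate peak learning rate.
#' @param warmup_fraction fraction of steps used for warmup.
#' @return numeric vector of length `total_steps`.
#' @export
lr_schedule <- function(total_steps, learning_rate = 3e-5,
                        warmup_fraction = 0.10) {
  T <- as.integer(total_steps)
  W <- max(1L, ceiling(warmup_fraction * T))
  t <- seq_len(T)
  ifelse(t <= W, learning_rate * t / W,
         learning_rate * (T - t) / max(1L, T - W))
}

#' Train a model
#'
#' Minimizes cross-entropy with the adaptive-moment optimizer (beta1 0.9,
#' beta2 0.999) under the warmup/decay schedule of [lr_schedule()]. The
#' gradients of the attention scoring vectors are smoothed through
#' [ewma_update()] with coefficient `rho` before the optimizer step. Data
#' are reshuffled every epoch; every source of randomness (initialization,
#' shuffling, dropout) is governed by `config$seeds`, so two runs with the
#' same seeds produce identical parameters.
#'
#' @param model a [model_init()] result.
#' @param dataset list of [encode()] results with non-`NULL` labels.
#' @param quiet suppress the per-epoch progress line.
#' @return the trained model, with a `history` attribute: per-step `loss`
#'   and `lr`.
#' @export
model_train <- function(model, dataset, quiet = TRUE) {
  cfg <- model$config
  n <- length(dataset)
  if (n == 0L) stop("empty training dataset")
  labs <- lapply(dataset, `[[`, "label")
  if (any(vapply(labs, is.null, logical(1))))
    stop("all training sequences need labels")
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  T_total <- cfg$epochs * steps_per_epoch
  lrs <- lr_schedule(T_total, cfg$learning_rate, cfg$warmup_fraction)

  paths <- leaf_paths(model)
  names(paths) <- vapply(paths, leaf_name, character(1))
  opt <- list(m = lapply(paths, function(p) get_leaf(model, p) * 0),
              v = lapply(paths, function(p) get_leaf(model, p) * 0))
  ewma_buf <- list()
  ewma_leaves <- grep("(wq_vec|wk_vec)$", names(paths), value = TRUE)
  for (nm in ewma_leaves) ewma_buf[[nm]] <- get_leaf(model, paths[[nm]]) * 0

  losses <- numeric(T_total)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(cfg$seeds$shuffle + epoch)
    perm <- sample.int(n)
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      idx <- perm[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
      batch <- dataset[idx]
      set.seed(cfg$seeds$dropout + step)
      fw <- model_forward_batch(model, batch, training = TRUE)
      y <- if (cfg$task_mode == "multilabel") {
        do.call(rbind, lapply(batch, `[[`, "label"))
      } else vapply(batch, `[[`, numeric(1), "label")
      ls <- model_loss(fw, y, cfg$task_mode)
      if (!is.finite(ls$loss))
        stop(sprintf("non-finite loss at step %d (epoch %d)", step, epoch))
      losses[step] <- ls$loss
      grads <- model_backward_batch(model, fw, ls$dlogits,
                                    sparse_tables = TRUE)
      lr <- lrs[step]
      for (nm in names(paths)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        if (is.list(g)) {
          # lazy sparse-row adaptive update for the embedding tables:
          # rows absent from the batch keep their state and value
          r <- g$rows
          if (length(r) == 0L) next
          gv <- g$vals
          opt$m[[nm]][r, ] <- b1 * opt$m[[nm]][r, , drop = FALSE] + (1 - b1) * gv
          opt$v[[nm]][r, ] <- b2 * opt$v[[nm]][r, , drop = FALSE] + (1 - b2) * gv * gv
          mhat <- opt$m[[nm]][r, , drop = FALSE] / (1 - b1^step)
          vhat <- opt$v[[nm]][r, , drop = FALSE] / (1 - b2^step)
          upd <- get_leaf(model, paths[[nm]])
          upd[r, ] <- upd[r, , drop = FALSE] - lr * mhat / (sqrt(vhat) + eps)
          model <- set_leaf(model, paths[[nm]], upd)
          next
        }
        if (nm %in% ewma_leaves) {
          g <- ewma_update(ewma_buf[[nm]], g, cfg$rho)
          ewma_buf[[nm]] <- g
        }
        opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
        opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
        mhat <- opt$m[[nm]] / (1 - b1^step)
        vhat <- opt$v[[nm]] / (1 - b2^step)
        upd <- get_leaf(model, paths[[nm]]) - lr * mhat / (sqrt(vhat) + eps)
        model <- set_leaf(model, paths[[nm]], upd)
      }
    }
    if (!quiet)
      message(sprintf("epoch %d/%d  mean loss %.5f", epoch, cfg$epochs,
                      mean(losses[(step - steps_per_epoch + 1L):step])))
  }
  attr(model, "history") <- list(loss = losses, lr = lrs)
  model
}

#' Predict labels for raw texts
#'
#' Runs the full pipeline (normalization, encoding with the model's
#' vocabulary, forward pass) and applies the decision rule: probability at
#' or above the threshold means positive for binary/multilabel tasks;
#' multiclass takes the arg-max with ties broken toward the lower class
#' index.
#'
#' @param model a trained `tf_model`.
#' @param texts character vector of raw texts (or a data frame with a
#'   `text` column).
#' @param batch_size forward batch size.
#' @return integer labels (binary/multiclass) or a 0/1 matrix (multilabel).
#' @export
model_predict <- function(model, texts, batch_size = 64L) {
  if (is.data.frame(texts)) texts <- texts$text
  if (length(texts) == 0L) return(integer(0))
  probs <- model_predict_proba(model, texts, batch_size)
  decide_labels(probs, model$config)
}

#' Predicted class probabilities for raw texts
#'
#' @inheritParams model_predict
#' @return numeric matrix of probabilities (one column for binary).
#' @export
model_predict_proba <- function(model, texts, batch_size = 64L) {
  if (is.data.frame(texts)) texts <- texts$text
  if (length(texts) == 0L) return(matrix(0, 0L, 1L))
  clean <- normalize_text(texts)
  seqs <- lapply(clean, encode, vocab = model$vocab,
                 max_len = model$config$max_len)
  out <- NULL
  for (start in seq(1L, length(seqs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(seqs))
    fw <- model_forward_batch(model, seqs[idx], training = FALSE)
    out <- rbind(out, fw$probs)
  }
  out
}

decide_labels <- function(probs, cfg) {
  if (cfg$task_mode == "multiclass") {
    as.integer(apply(probs, 1L, which.max) - 1L)
  } else if (cfg$task_mode == "multilabel") {
    (probs >= cfg$threshold) * 1L
  } else {
    as.integer(probs[, 1L] >= cfg$threshold)
  }
}
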