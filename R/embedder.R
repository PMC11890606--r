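#' Initialize embedding tables
#'
#' Word, subunit and positional rows are drawn i.i.d. normal with standard
#' deviation 0.1, so both halves of the concatenated word+position vector
#' start on the same scale — word vectors trained from scratch here stand
#' in for pretrained 300-dimensional vectors, whose entries are of this
#' order. The padding row (id 0) of the word table is zero and stays
#' frozen. The positional
#' table holds one vector per position up to `max_len` and is frozen by
#' default: positions are represented by fixed random vectors, resampled
#' never — only the seed determines them.
#'
#' @param vocab a [build_vocab()] result.
#' @param max_len maximum sequence length (rows of the positional table;
#'   default 128).
#' @param dim embedding width (default 300; the concatenated word+position
#'   vector then has width 600).
#' @param seed integer seed; tables are fully determined by it.
#' @param train_positions should the positional table receive gradient
#'   updates (default `FALSE`)?
#' @return list of class `tf_embedding_tables`: `word_table`,
#'   `subunit_table`, `position_table`, `trainable`, `dim`, `max_len`,
#'   `seed`.
#' @export
init_tables <- function(vocab, max_len = 128L, dim = 300L, seed = 1L,
                        train_positions = FALSE) {
  max_len <- as.integer(max_len); dim <- as.integer(dim)
  if (dim < 1L || max_len < 1L) stop("dim and max_len must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  nw <- n_word_rows(vocab)
  ns <- n_subunit_rows(vocab)
  word_table <- matrix(stats::rnorm(nw * dim, sd = 0.1), nw, dim)
  word_table[1L, ] <- 0                     # padding row, frozen
  subunit_table <- matrix(stats::rnorm(ns * dim, sd = 0.1), ns, dim)
  position_table <- matrix(stats::rnorm(max_len * dim, sd = 0.1), max_len, dim)
  structure(list(word_table = word_table, subunit_table = subunit_table,
                 position_table = position_table,
                 trainable = c(word = TRUE, subunit = TRUE,
                               position = isTRUE(train_positions)),
                 dim = dim, max_len = max_len, seed = as.integer(seed)),
            class = "tf_embedding_tables")
}

#' Word vector for one position of a token sequence
#'
#' In-vocabulary tokens look up their word-table row; out-of-vocabulary
#' tokens return the elementwise sum of their subunit rows.
#'
#' @param seq a [encode()] result.
#' @param t position (1-based); must be a real (unmasked) position.
#' @param tables a [init_tables()] result.
#' @return numeric vector of length `tables$dim`.
#' @export
word_vector <- function(seq, t, tables) {
  if (t < 1L || t > length(seq$mask) || !seq$mask[t])
    stop("padding has no word vector")
  key <- as.character(t)
  if (!is.null(seq$oov_map[[key]])) {
    rows <- tables$subunit_table[seq$oov_map[[key]] + 1L, , drop = FALSE]
    colSums(rows)
  } else {
    tables$word_table[seq$ids[t] + 1L, ]
  }
}

#' Embed a token sequence as a position-augmented matrix
#'
#' Row `t` is the end-to-end concatenation of the token's word vector
#' (first `dim` columns, depending only on token identity) and the
#' positional vector for `t` (last `dim` columns, depending only on `t`).
#' Padding rows are zero.
#'
#' @param seq a [encode()] result.
#' @param tables a [init_tables()] result.
#' @param use_position if `FALSE` (ablation), the word vector is duplicated
#'   into the last `dim` columns instead of the positional vector, keeping
#'   the output width unchanged.
#' @return numeric matrix `max_len x 2*dim`.
#' @export
embed_sequence <- function(seq, tables, use_position = TRUE) {
  L <- length(seq$ids)
  d <- tables$dim
  out <- matrix(0, L, 2L * d)
  for (t in seq_len(L)) {
    if (!seq$mask[t]) next
    wv <- word_vector(seq, t, tables)
    out[t, 1:d] <- wv
    out[t, (d + 1L):(2L * d)] <- if (use_position) tables$position_table[t, ] else wv
  }
  out
}

# Batched embedding over a list of sequences, trimmed to L positions.
# Slot r = (t-1)*B + b holds position t of sequence b (column-major over the
# batch), which lets per-sequence reductions use rowsum() with group
# rep(1:B, L). Returns the matrix plus the bookkeeping needed to scatter
# gradients back into the tables.
embed_batch <- function(seqs, tables, L, use_position = TRUE) {
  B <- length(seqs)
  d <- tables$dim
  ids <- matrix(0L, B, L)       # word row index (1-based); 0 = OOV or pad
  mask <- matrix(FALSE, B, L)
  oov_slots <- integer(0)
  oov_units <- list()
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    n <- min(s$n_tokens, L)
    if (n > 0L) mask[b, seq_len(n)] <- TRUE
    for (t in seq_len(n)) {
      key <- as.character(t)
      if (!is.null(s$oov_map[[key]])) {
        oov_slots <- c(oov_slots, (t - 1L) * B + b)
        oov_units[[length(oov_units) + 1L]] <- s$oov_map[[key]] + 1L
      } else {
        ids[b, t] <- s$ids[t] + 1L
      }
    }
  }
  flat_ids <- as.vector(ids)    # slot-ordered: b fastest, t slower
  W <- matrix(0, B * L, d)
  known <- flat_ids > 0L
  W[known, ] <- tables$word_table[flat_ids[known], , drop = FALSE]
  for (j in seq_along(oov_slots)) {
    u <- oov_units[[j]]
    W[oov_slots[j], ] <- colSums(tables$subunit_table[u, , drop = FALSE])
  }
  P <- if (use_position) {
    tables$position_table[rep(seq_len(L), each = B), , drop = FALSE] *
      as.numeric(mask)
  } else W
  X <- cbind(W, P)
  list(X = X, mask = as.vector(mask), flat_ids = flat_ids,
       oov_slots = oov_slots, oov_units = oov_units, B = B, L = L)
}

# Scatter the gradient of the batched embedding back into table gradients.
# dX: (B*L) x 2d. Word/subunit gradients are row-sparse (few rows of the
# tables are touched per batch); they are returned as list(rows, vals) and
# densified only when `dense = TRUE` (gradient checking).
embed_batch_backward <- function(dX, emb, tables, use_position = TRUE,
                                 dense = FALSE) {
  d <- tables$dim
  dW <- dX[, 1:d, drop = FALSE]
  dP <- dX[, (d + 1L):(2L * d), drop = FALSE]
  if (!use_position) dW <- dW + dP
  known <- emb$flat_ids > 0L & emb$mask
  if (any(known)) {
    agg <- rowsum(dW[known, , drop = FALSE], group = emb$flat_ids[known])
    w_rows <- as.integer(rownames(agg))
    keep <- w_rows != 1L                     # padding row frozen
    dword <- list(rows = w_rows[keep], vals = agg[keep, , drop = FALSE])
  } else {
    dword <- list(rows = integer(0), vals = matrix(0, 0, d))
  }
  if (length(emb$oov_slots)) {
    reps <- lengths(emb$oov_units)
    all_units <- unlist(emb$oov_units)
    gsub_ <- dW[rep(emb$oov_slots, reps), , drop = FALSE]
    agg <- rowsum(gsub_, group = all_units)
    dsub <- list(rows = as.integer(rownames(agg)), vals = agg)
  } else {
    dsub <- list(rows = integer(0), vals = matrix(0, 0, d))
  }
  dpos <- NULL
  if (use_position && tables$trainable[["position"]]) {
    dPm <- dP * emb$mask
    agg <- rowsum(dPm, group = rep(seq_len(emb$L), each = emb$B))
    dpos <- matrix(0, nrow(tables$position_table), d)
    dpos[as.integer(rownames(agg)), ] <- agg
  }
  if (dense) {
    densify <- function(sp, nr) {
      out <- matrix(0, nr, d)
      if (length(sp$rows)) out[sp$rows, ] <- sp$vals
      out
    }
    dword <- densify(dword, nrow(tables$word_table))
    dsub <- densify(dsub, nrow(tables$subunit_table))
  }
  list(word = dword, subunit = dsub, position = dpos)
}

#' Load word vectors in word2vec text format
#'
#' Reads the plain-text format (`V dim` header line, then one
#' `word v1 ... v_dim` line per word) and overwrites the word-table rows of
#' words present in the vocabulary; other rows keep their random
#' initialization.
#'
#' @param path word2vec text file.
#' @param tables a [init_tables()] result.
#' @param vocab the matching [build_vocab()] result.
#' @return `tables` with updated `word_table`; the number of rows loaded is
#'   attached as `attr(,"n_loaded")`.
#' @export
load_word2vec <- function(path, tables, vocab) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty word2vec file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed word2vec header: ", lines[1])
  if (hdr[2] != tables$dim)
    stop(sprintf("vector width %d does not match table dim %d", hdr[2], tables$dim))
  n_loaded <- 0L
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    w <- parts[1]
    id <- vocab$word_to_id[w]
    if (is.na(id)) next
    v <- as.numeric(parts[-1])
    if (length(v) != tables$dim || anyNA(v))
      stop("malformed word2vec row for word: ", w)
    tables$word_table[id + 1L, ] <- v
    n_loaded <- n_loaded + 1L
  }
  attr(tables, "n_loaded") <- n_loaded
  tables
}
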