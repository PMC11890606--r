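#' Build a word + character-subunit vocabulary
#'
#' Words with corpus frequency at least `min_count` get ids (in order of
#' first appearance, so the result is deterministic given corpus order).
#' The subunit inventory holds every character 3- to 6-gram occurring at
#' least `min_count` times across word occurrences, plus every single
#' character seen at build time, so out-of-vocabulary segmentation can
#' never fail. Id 0 is reserved for padding and id 1 for the unknown
#' subunit.
#'
#' @param corpus character vector of normalized texts, or a data frame with
#'   a `text` column (see [normalize_corpus()]).
#' @param min_count minimum corpus frequency for a word or n-gram
#'   (default 1).
#' @return An object of class `tf_vocabulary`: lists `word_to_id` and
#'   `subunit_to_id` (named integer vectors), their inverses, and
#'   `min_count`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  if (is.data.frame(corpus)) corpus <- corpus$text
  corpus <- as.character(corpus)
  if (length(corpus) == 0L) stop("empty corpus")
  min_count <- as.integer(min_count)
  stopifnot(min_count >= 1L)

  toks <- unlist(stringi::stri_split_fixed(corpus, " ", omit_empty = TRUE))
  if (length(toks) == 0L) stop("empty corpus")

  first_seen <- !duplicated(toks)
  counts <- table(factor(toks, levels = toks[first_seen]))
  keep <- names(counts)[counts >= min_count]
  # preserve first-appearance order
  keep <- toks[first_seen][toks[first_seen] %in% keep]
  word_ids <- seq_along(keep) + 1L          # 0 = pad, 1 = unknown subunit
  names(word_ids) <- keep

  # subunit inventory: single chars (always) + 3..6-grams above threshold,
  # counted over token occurrences
  chars <- unlist(stringi::stri_split_boundaries(toks, type = "character"))
  char_inv <- unique(chars)
  ngrams <- character(0)
  distinct <- toks[first_seen]
  wc <- as.integer(counts)
  ng_counts <- new.env(parent = emptyenv())
  for (i in seq_along(distinct)) {
    w <- distinct[i]
    nc <- stringi::stri_length(w)
    if (nc < 3L) next
    for (n in 3L:min(6L, nc)) {
      for (s in 1L:(nc - n + 1L)) {
        g <- stringi::stri_sub(w, s, s + n - 1L)
        ng_counts[[g]] <- (if (is.null(ng_counts[[g]])) 0L else ng_counts[[g]]) + wc[i]
      }
    }
  }
  if (length(ls(ng_counts, all.names = TRUE))) {
    gs <- sort(ls(ng_counts, all.names = TRUE))
    cs <- vapply(gs, function(g) ng_counts[[g]], integer(1))
    ngrams <- gs[cs >= min_count]
  }
  subunits <- c(sort(char_inv), sort(ngrams))
  subunit_ids <- seq_along(subunits) + 1L   # 1 = unknown subunit
  names(subunit_ids) <- subunits

  structure(list(word_to_id = word_ids,
                 id_to_word = stats::setNames(names(word_ids), word_ids),
                 subunit_to_id = subunit_ids,
                 min_count = min_count),
            class = "tf_vocabulary")
}

#' @export
print.tf_vocabulary <- function(x, ...) {
  cat(sprintf("<tf_vocabulary> %d words, %d subunits (min_count=%d)\n",
              length(x$word_to_id), length(x$subunit_to_id), x$min_count))
  invisible(x)
}

n_word_rows <- function(vocab) length(vocab$word_to_id) + 2L
n_subunit_rows <- function(vocab) length(vocab$subunit_to_id) + 2L

#' Segment an out-of-vocabulary word into subunit ids
#'
#' Greedy left-to-right longest-match segmentation against the vocabulary's
#' character n-gram inventory (lengths 6 down to 1). Characters never seen
#' at build time map to the unknown-subunit id 1, so segmentation always
#' terminates with full coverage.
#'
#' @param word non-empty string absent from `vocab$word_to_id`.
#' @param vocab a [build_vocab()] result.
#' @return integer vector of subunit ids.
#' @export
segment_oov <- function(word, vocab) {
  word <- as.character(word)
  nc <- stringi::stri_length(word)
  if (is.na(nc) || nc == 0L) stop("cannot segment an empty word")
  sub_ids <- vocab$subunit_to_id
  out <- integer(0)
  i <- 1L
  while (i <= nc) {
    matched <- FALSE
    for (n in min(6L, nc - i + 1L):1L) {
      g <- stringi::stri_sub(word, i, i + n - 1L)
      id <- sub_ids[g]
      if (!is.na(id)) {
        out <- c(out, unname(id))
        i <- i + n
        matched <- TRUE
        break
      }
    }
    if (!matched) {           # character absent from inventory
      out <- c(out, 1L)
      i <- i + 1L
    }
  }
  out
}

#' Encode a normalized document as a fixed-length token sequence
#'
#' Whitespace-split tokens are mapped to word ids, right-truncated at
#' `max_len`, and padded with id 0 (mask `FALSE`). Out-of-vocabulary tokens
#' are flagged and their [segment_oov()] decomposition stored in `oov_map`.
#'
#' @param doc a single normalized text, or a one-row data frame with
#'   columns `text` and optionally `label`.
#' @param vocab a [build_vocab()] result.
#' @param max_len maximum sequence length (default 128).
#' @param label optional integer class label.
#' @return An object of class `tf_token_sequence`: integer `ids` and logical
#'   `mask` of length `max_len`, `oov_map` (list indexed by position as
#'   character keys), `tokens`, `label`, `n_tokens`.
#' @export
encode <- function(doc, vocab, max_len = 128L, label = NULL) {
  if (is.data.frame(doc)) {
    if (is.null(label) && "label" %in% names(doc)) label <- doc$label[1]
    doc <- doc$text[1]
  }
  max_len <- as.integer(max_len)
  stopifnot(max_len >= 1L)
  toks <- stringi::stri_split_fixed(doc, " ", omit_empty = TRUE)[[1]]
  toks <- utils::head(toks, max_len)
  n <- length(toks)
  ids <- integer(max_len)
  mask <- logical(max_len)
  oov_map <- list()
  if (n > 0L) {
    wid <- vocab$word_to_id[toks]
    mask[seq_len(n)] <- TRUE
    for (t in seq_len(n)) {
      if (is.na(wid[t])) {
        ids[t] <- 1L                       # unknown-word marker id
        oov_map[[as.character(t)]] <- segment_oov(toks[t], vocab)
      } else {
        ids[t] <- unname(wid[t])
      }
    }
  }
  structure(list(ids = ids, mask = mask, oov_map = oov_map,
                 tokens = toks, label = label, n_tokens = n),
            class = "tf_token_sequence")
}

#' Encode a corpus of normalized documents
#'
#' @param docs data frame with columns `id`, `text` and optionally `label`.
#' @param vocab a [build_vocab()] result.
#' @param max_len maximum sequence length (default 128).
#' @return list of [encode()] results.
#' @export
encode_corpus <- function(docs, vocab, max_len = 128L) {
  labels <- if ("label" %in% names(docs)) docs$label else rep(list(NULL), nrow(docs))
  lapply(seq_len(nrow(docs)), function(i) {
    encode(docs$text[i], vocab, max_len,
           label = if (is.list(labels)) labels[[i]] else labels[i])
  })
}

#' Decode word ids back to tokens
#'
#' Inverse of [encode()] for in-vocabulary positions; OOV and padding
#' positions decode to `NA`.
#'
#' @param ids integer vector of word ids.
#' @param vocab a [build_vocab()] result.
#' @return character vector.
#' @export
decode_ids <- function(ids, vocab) {
  out <- vocab$id_to_word[as.character(ids)]
  unname(out)
}

#' Write a vocabulary to a versioned two-section text file
#'
#' @param vocab a [build_vocab()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_vocabulary <- function(vocab, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("tweetformer-vocab\tv1", sprintf("min_count\t%d", vocab$min_count),
               "[words]"), con)
  writeLines(sprintf("%s\t%d", names(vocab$word_to_id), vocab$word_to_id), con)
  writeLines("[subunits]", con)
  writeLines(sprintf("%s\t%d", names(vocab$subunit_to_id), vocab$subunit_to_id), con)
  invisible(path)
}

#' Read a vocabulary written by [save_vocabulary()]
#'
#' @param path file path.
#' @return a `tf_vocabulary` object.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L || !startsWith(lines[1], "tweetformer-vocab"))
    stop("not a tweetformer vocabulary file: ", path)
  min_count <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][2])
  iw <- which(lines == "[words]")
  is <- which(lines == "[subunits]")
  parse_sec <- function(sec) {
    if (length(sec) == 0L) return(stats::setNames(integer(0), character(0)))
    parts <- stringi::stri_split_fixed(sec, "\t")
    stats::setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                    vapply(parts, `[`, character(1), 1))
  }
  word_ids <- parse_sec(lines[seq.int(iw + 1L, is - 1L)])
  sub_ids <- parse_sec(if (is < length(lines)) lines[seq.int(is + 1L, length(lines))] else character(0))
  structure(list(word_to_id = word_ids,
                 id_to_word = stats::setNames(names(word_ids), word_ids),
                 subunit_to_id = sub_ids,
                 min_count = min_count),
            class = "tf_vocabulary")
}
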