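#' Specification for a synthetic tweet-like corpus
#'
#' Describes a labelled corpus of short noisy texts with a class-dependent
#' keyword signal: each class owns a small disjoint set of marker words
#' (standing in for, e.g., adverse-drug-reaction phrases), injected with
#' probability `signal_strength` into documents of that class on top of a
#' shared Zipf-distributed background vocabulary. Noise matches what the
#' normalization pipeline expects from tweets: URLs, emoji, elongated
#' words, and novel out-of-vocabulary strings.
#'
#' @param n_docs number of documents.
#' @param n_classes number of classes (labels `0..n_classes-1`).
#' @param vocab_size size of the shared background vocabulary.
#' @param doc_length integer pair: inclusive range of background words per
#'   document.
#' @param signal_strength probability that a document of class `c` contains
#'   1-3 marker words of class `c`.
#' @param oov_rate probability a document carries one novel
#'   out-of-vocabulary string.
#' @param url_rate probability a document carries a URL.
#' @param emoji_rate probability a document carries an emoji.
#' @param elongation_rate probability one word of the document is elongated
#'   ("sooo"-style).
#' @param markers_per_class size of each class's marker set.
#' @param zipf_exponent exponent of the background word-rank distribution.
#' @param seed integer seed; the corpus is fully determined by it.
#' @return list of class `tf_synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 2000L, n_classes = 2L, vocab_size = 500L,
                           doc_length = c(6L, 18L), signal_strength = 0.9,
                           oov_rate = 0.1, url_rate = 0.2, emoji_rate = 0.2,
                           elongation_rate = 0.1, markers_per_class = 6L,
                           zipf_exponent = 1.1, seed = 1L) {
  rates <- c(signal_strength, oov_rate, url_rate, emoji_rate, elongation_rate)
  stopifnot(all(rates >= 0 & rates <= 1), n_docs >= n_classes,
            length(doc_length) == 2L, all(doc_length >= 1L),
            doc_length[1] <= doc_length[2], vocab_size >= 10L,
            markers_per_class >= 1L, n_classes >= 2L)
  structure(list(n_docs = as.integer(n_docs), n_classes = as.integer(n_classes),
                 vocab_size = as.integer(vocab_size),
                 doc_length = as.integer(doc_length),
                 signal_strength = signal_strength, oov_rate = oov_rate,
                 url_rate = url_rate, emoji_rate = emoji_rate,
                 elongation_rate = elongation_rate,
                 markers_per_class = as.integer(markers_per_class),
                 zipf_exponent = zipf_exponent, seed = as.integer(seed)),
            class = "tf_synthetic_spec")
}

random_words <- function(n, min_len = 3L, max_len = 8L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(letters, l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a seeded synthetic tweet-like corpus
#'
#' See [synthetic_spec()] for the generative model. Marker sets are disjoint
#' across classes and disjoint from the background vocabulary, so the
#' Bayes-optimal positive-class F1 approaches 1 as `signal_strength`
#' approaches 1. The global RNG state is saved and restored.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with columns `id`, `text` (raw, pre-normalization),
#'   `label`; the per-class marker sets are attached as
#'   `attr(corpus, "markers")` and the spec as `attr(corpus, "spec")`.
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "tf_synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  # background vocabulary + disjoint marker sets, all distinct words
  need <- spec$vocab_size + spec$n_classes * spec$markers_per_class
  words <- unique(random_words(need * 3L))
  if (length(words) < need) stop("vocabulary collision; increase word length")
  words <- words[seq_len(need)]
  background <- words[seq_len(spec$vocab_size)]
  markers <- split(words[(spec$vocab_size + 1L):need],
                   rep(seq_len(spec$n_classes), each = spec$markers_per_class))
  names(markers) <- as.character(seq_len(spec$n_classes) - 1L)

  zipf_w <- (seq_len(spec$vocab_size))^(-spec$zipf_exponent)
  zipf_w <- zipf_w / sum(zipf_w)
  emojis <- emoji_table()$chars

  labels <- sample.int(spec$n_classes, spec$n_docs, replace = TRUE) - 1L
  texts <- character(spec$n_docs)
  oov_flags <- logical(spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    len <- sample(spec$doc_length[1]:spec$doc_length[2], 1L)
    toks <- sample(background, len, replace = TRUE, prob = zipf_w)
    if (stats::runif(1) < spec$signal_strength) {
      k <- sample(1:3, 1L)
      mk <- sample(markers[[as.character(labels[i])]], k, replace = TRUE)
      pos <- sort(sample.int(len + 1L, k, replace = TRUE))
      for (j in seq_len(k)) toks <- append(toks, mk[j], after = pos[j] - 1L + j - 1L)
    }
    if (stats::runif(1) < spec$elongation_rate && length(toks) > 0L) {
      t0 <- sample.int(length(toks), 1L)
      w <- toks[t0]
      ch <- sample.int(nchar(w), 1L)
      toks[t0] <- paste0(substr(w, 1L, ch),
                         paste(rep(substr(w, ch, ch), sample(2:4, 1L)), collapse = ""),
                         substr(w, ch + 1L, nchar(w)))
    }
    if (stats::runif(1) < spec$oov_rate) {
      novel <- paste0("zq", paste(sample(letters, 8L, replace = TRUE), collapse = ""))
      toks <- append(toks, novel, after = sample.int(length(toks) + 1L, 1L) - 1L)
      oov_flags[i] <- TRUE
    }
    if (stats::runif(1) < spec$url_rate) {
      url <- paste0("https://t.co/", paste(sample(c(letters, 0:9), 8L, replace = TRUE), collapse = ""))
      toks <- append(toks, url, after = sample.int(length(toks) + 1L, 1L) - 1L)
    }
    if (stats::runif(1) < spec$emoji_rate) {
      toks <- append(toks, sample(emojis, 1L),
                     after = sample.int(length(toks) + 1L, 1L) - 1L)
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  out <- data.frame(id = sprintf("doc%06d", seq_len(spec$n_docs)),
                    text = texts, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "markers") <- markers
  attr(out, "spec") <- spec
  attr(out, "oov_flags") <- oov_flags
  out
}

#' Reference confusion counts for two tweet-classification benchmarks
#'
#' Reported error-analysis counts for a flu-vaccination-mention task
#' (`smm4h18_task4`: tp=802, fp=183, fn=99) and a three-class
#' medication-intake task scored on the pooled intake classes
#' (`smm4h17_task2`: tp=2854, fp=1013, fn=1241). Used as worked examples
#' for the metric functions: the first yields precision 0.814, recall
#' 0.890, F1 0.850; the second yields recall 0.697 and F1 0.717.
#'
#' @return named list of `tf_confusion` objects.
#' @export
benchmark_confusion_counts <- function() {
  list(smm4h18_task4 = confusion_counts(tp = 802L, fp = 183L, fn = 99L),
       smm4h17_task2 = confusion_counts(tp = 2854L, fp = 1013L, fn = 1241L))
}
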