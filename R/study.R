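#' End-to-end learning study on a synthetic corpus
#'
#' Generates a seeded synthetic corpus, holds out 20% of it, trains a
#' model variant under the default recipe (3 epochs, learning rate 3e-5,
#' batch 64) and reports held-out positive-class metrics. This is the
#' driver behind the package's learning-capability and ablation checks.
#'
#' @param seed integer; controls corpus generation, the split and all
#'   model seeds.
#' @param variant `"full"`, `"no_position"` or `"no_bilstm"`.
#' @param n_docs corpus size (default 2000).
#' @param signal_strength marker-injection probability (default 0.9).
#' @param positive_class label scored as positive (default 1).
#' @param config_overrides named list merged into [model_config()]
#'   arguments.
#' @return list with `f1`, `precision`, `recall` (at the configured 0.5
#'   threshold), `auc` and `best_f1` (threshold-free ranking quality of the
#'   same predictions), `final_loss`, `initial_loss`, `n_train`, `n_test`,
#'   `variant`, `seed`.
#' @export
learning_study <- function(seed = 1L, variant = c("full", "no_position",
                                                  "no_bilstm"),
                           n_docs = 2000L, signal_strength = 0.9,
                           positive_class = 1L, config_overrides = list()) {
  variant <- match.arg(variant)
  spec <- synthetic_spec(n_docs = n_docs, n_classes = 2L,
                         signal_strength = signal_strength, seed = seed)
  corpus <- generate_corpus(spec)
  clean <- normalize_corpus(corpus)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 10000L)
  n_test <- round(0.2 * nrow(clean))
  test_idx <- sample.int(nrow(clean), n_test)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  train <- clean[-test_idx, , drop = FALSE]
  test_raw <- corpus[test_idx, , drop = FALSE]

  args <- utils::modifyList(
    list(n_classes = 2L, task_mode = "binary",
         seeds = list(init = seed, shuffle = seed + 1L, dropout = seed + 2L),
         use_position_vector = variant != "no_position",
         use_bilstm = variant != "no_bilstm"),
    config_overrides)
  config <- do.call(model_config, args)

  vocab <- build_vocab(train, min_count = config$min_count)
  model <- model_init(vocab, config)
  seqs <- encode_corpus(train, vocab, config$max_len)
  model <- model_train(model, seqs)
  hist <- attr(model, "history")

  probs <- model_predict_proba(model, test_raw)[, 1L]
  pred <- as.integer(probs >= config$threshold)
  m <- precision_recall_f1(confusion(test_raw$label, pred, positive_class))
  pos <- probs[test_raw$label == positive_class]
  neg <- probs[test_raw$label != positive_class]
  auc <- mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
  best_f1 <- max(vapply(sort(unique(probs)), function(th) {
    precision_recall_f1(confusion(test_raw$label,
                                  as.integer(probs >= th),
                                  positive_class))$f1
  }, numeric(1)))
  spe <- ceiling(length(seqs) / config$batch_size)
  list(f1 = m$f1, precision = m$precision, recall = m$recall,
       auc = auc, best_f1 = best_f1,
       initial_loss = mean(utils::head(hist$loss, spe)),
       final_loss = mean(utils::tail(hist$loss, spe)),
       n_train = length(seqs), n_test = n_test,
       variant = variant, seed = seed, model = model)
}
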