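escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_field <- function(x) {
  x <- gsub("\\\\", "\x01", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  gsub("\x01", "\\", x, fixed = TRUE)
}

#' Read a labelled text dataset from TSV
#'
#' Expects a UTF-8 file with header `id<TAB>text<TAB>label` (the `label`
#' column may be absent for prediction inputs). Tabs and newlines embedded
#' in text must be escaped as `\\t` / `\\n`. Malformed rows raise an error
#' naming the line number.
#'
#' @param path input file.
#' @param labelled `TRUE` to require labels, `FALSE` to forbid them, `NA`
#'   (default) to accept either.
#' @return data frame with columns `id`, `text` and, when present,
#'   integer `label`.
#' @export
read_dataset <- function(path, labelled = NA) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty dataset file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_label <- length(header) >= 3L && header[3] == "label"
  if (!identical(header[1:2], c("id", "text")))
    stop("line 1: expected header starting with 'id\\ttext'")
  if (isTRUE(labelled) && !has_label) stop("dataset has no label column: ", path)
  if (isFALSE(labelled)) has_label <- FALSE
  ncol_exp <- if (has_label) 3L else 2L
  body <- lines[-1]
  parts <- stringi::stri_split_fixed(body, "\t")
  bad <- which(vapply(parts, length, integer(1)) != ncol_exp)
  if (length(bad))
    stop(sprintf("line %d: expected %d columns", bad[1] + 1L, ncol_exp))
  out <- data.frame(id = vapply(parts, `[`, character(1), 1),
                    text = unescape_field(vapply(parts, `[`, character(1), 2)),
                    stringsAsFactors = FALSE)
  if (has_label) {
    raw <- vapply(parts, `[`, character(1), 3)
    lab <- suppressWarnings(as.integer(raw))
    if (anyNA(lab))
      stop(sprintf("line %d: unknown label value '%s'",
                   which(is.na(lab))[1] + 1L, raw[which(is.na(lab))[1]]))
    out$label <- lab
  }
  out
}

#' Write a dataset as TSV
#'
#' Inverse of [read_dataset()]; tabs, newlines and backslashes in text are
#' escaped so the round trip is byte-identical for well-formed files.
#'
#' @param docs data frame with `id`, `text` and optionally `label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(docs, path) {
  has_label <- "label" %in% names(docs)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(if (has_label) "id\ttext\tlabel" else "id\ttext", con)
  txt <- escape_field(docs$text)
  if (has_label) {
    writeLines(sprintf("%s\t%s\t%d", docs$id, txt, docs$label), con)
  } else {
    writeLines(sprintf("%s\t%s", docs$id, txt), con)
  }
  invisible(path)
}

# --- checkpointing ---------------------------------------------------------

all_param_paths <- function(model) {
  p <- list(c("tables", "word_table"), c("tables", "subunit_table"),
            c("tables", "position_table"),
            c("ctx", "in_proj_W"), c("ctx", "in_proj_b"),
            c("ctx", "fusion_logits"))
  for (ly in c("layer1", "layer2"))
    for (dr in c("fwd", "bwd"))
      for (m in c("Wx", "Wh", "b"))
        p <- c(p, list(c("ctx", ly, dr, m)))
  for (k in seq_along(model$enc))
    for (m in c("Wq", "Wk", "Wv", "wq_vec", "wk_vec", "Wr", "br",
                "out_W", "out_b"))
      p <- c(p, list(c("enc", as.character(k), m)))
  c(p, list("dense_W", "dense_b"))
}

#' Save a model checkpoint as portable text
#'
#' Single UTF-8 file: configuration as YAML, the vocabulary, and every
#' parameter array printed with 17 significant digits so that
#' save/load round-trips bit-exactly.
#'
#' @param model a `tf_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("tweetformer-checkpoint\tv1", con)
  writeLines("#config", con)
  cfg <- unclass(model$config)
  writeLines(yaml::as.yaml(cfg), con)
  writeLines("#vocab", con)
  writeLines(c("tweetformer-vocab\tv1",
               sprintf("min_count\t%d", model$vocab$min_count), "[words]"), con)
  writeLines(sprintf("%s\t%d", names(model$vocab$word_to_id),
                     model$vocab$word_to_id), con)
  writeLines("[subunits]", con)
  writeLines(sprintf("%s\t%d", names(model$vocab$subunit_to_id),
                     model$vocab$subunit_to_id), con)
  writeLines("#params", con)
  for (p in all_param_paths(model)) {
    v <- get_leaf(model, p)
    d <- if (is.null(dim(v))) length(v) else dim(v)
    writeLines(sprintf("[param %s %s]", leaf_name(p),
                       paste(d, collapse = " ")), con)
    vals <- sprintf("%.17g", as.vector(v))
    idx <- seq_along(vals)
    writeLines(tapply(vals, (idx - 1L) %/% 100L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint file.
#' @return a `tf_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1], "tweetformer-checkpoint"))
    stop("not a tweetformer checkpoint: ", path)
  sec <- function(tag) which(lines == tag)
  i_cfg <- sec("#config"); i_voc <- sec("#vocab"); i_par <- sec("#params")
  cfg <- yaml::yaml.load(paste(lines[(i_cfg + 1L):(i_voc - 1L)],
                               collapse = "\n"))
  cfg$seeds <- lapply(cfg$seeds, as.integer)
  config <- do.call(model_config, cfg[setdiff(names(cfg), "d_model")])
  voc_lines <- lines[(i_voc + 1L):(i_par - 1L)]
  tmp <- tempfile()
  writeLines(voc_lines, tmp)
  vocab <- load_vocabulary(tmp)
  unlink(tmp)
  model <- model_init(vocab, config)
  i <- i_par + 1L
  while (i <= length(lines)) {
    hdr <- lines[i]
    stopifnot(startsWith(hdr, "[param "))
    parts <- strsplit(sub("^\\[param (.*)\\]$", "\\1", hdr), " ")[[1]]
    nm <- parts[1]
    dims <- as.integer(parts[-1])
    n <- prod(dims)
    vals <- numeric(0)
    i <- i + 1L
    while (length(vals) < n) {
      vals <- c(vals, as.numeric(strsplit(lines[i], " ", fixed = TRUE)[[1]]))
      i <- i + 1L
    }
    v <- if (length(dims) == 1L) vals else array(vals, dims)
    model <- set_leaf(model, strsplit(nm, ".", fixed = TRUE)[[1]], v)
  }
  model
}

# --- command-line surface --------------------------------------------------

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}

flag <- function(flags, name, default = NULL) {
  if (!is.null(flags[[name]])) flags[[name]] else default
}

check_flags <- function(flags, allowed) {
  bad <- setdiff(names(flags), allowed)
  if (length(bad)) stop("unknown flag: --", bad[1])
}

cli_usage <- function() {
  paste("usage: tweetformer <preprocess|synth|train|predict|evaluate> [--flags]",
        "  preprocess --in data.tsv --out clean.tsv",
        "  synth      --n 2000 --classes 2 --seed 1 --out corpus.tsv",
        "  train      --train clean.tsv --out model.ckpt [--epochs 3]",
        "             [--batch-size 64] [--lr 3e-5] [--max-len 128] [--seed 1]",
        "             [--classes 2] [--vectors vec.txt] [--no-position] [--no-bilstm]",
        "  predict    --model model.ckpt --in data.tsv --out pred.tsv",
        "  evaluate   --pred pred.tsv --gold gold.tsv [--positive 1]",
        "             [--micro 1,2] [--out report.txt]",
        sep = "\n")
}

#' Run a command-line invocation
#'
#' Dispatches the subcommands `preprocess`, `synth`, `train`, `predict`
#' and `evaluate`, composing the package's modules. Every run prints the
#' seeds and configuration it used so it can be replayed exactly.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return integer exit status (0 on success), invisibly.
#' @export
run_command <- function(argv) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    cmd <- argv[1]
    flags <- parse_flags(argv[-1])
    switch(cmd,
      preprocess = cli_preprocess(flags),
      synth = cli_synth(flags),
      train = cli_train(flags),
      predict = cli_predict(flags),
      evaluate = cli_evaluate(flags),
      { message("unknown subcommand: ", cmd, "\n", cli_usage()); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_preprocess <- function(flags) {
  check_flags(flags, c("in", "out"))
  docs <- read_dataset(flag(flags, "in", stop("--in is required")))
  write_dataset(normalize_corpus(docs), flag(flags, "out", stop("--out is required")))
  0L
}

cli_synth <- function(flags) {
  check_flags(flags, c("n", "classes", "seed", "out"))
  spec <- synthetic_spec(n_docs = as.integer(flag(flags, "n", 1000L)),
                         n_classes = as.integer(flag(flags, "classes", 2L)),
                         seed = as.integer(flag(flags, "seed", 1L)))
  out <- flag(flags, "out", stop("--out is required"))
  write_dataset(generate_corpus(spec), out)
  yaml::write_yaml(unclass(spec), paste0(out, ".spec.yaml"))
  message(sprintf("wrote %d documents to %s (seed %d)", spec$n_docs, out,
                  spec$seed))
  0L
}

cli_train <- function(flags) {
  check_flags(flags, c("train", "out", "seed", "classes", "epochs",
                        "batch-size", "lr", "max-len", "vectors",
                        "no-position", "no-bilstm"))
  train_path <- flag(flags, "train", stop("--train is required"))
  out <- flag(flags, "out", stop("--out is required"))
  seed <- as.integer(flag(flags, "seed", 1L))
  docs <- normalize_corpus(read_dataset(train_path, labelled = TRUE))
  config <- model_config(
    n_classes = as.integer(flag(flags, "classes", 2L)),
    task_mode = if (as.integer(flag(flags, "classes", 2L)) > 2L) "multiclass" else "binary",
    epochs = as.integer(flag(flags, "epochs", 3L)),
    batch_size = as.integer(flag(flags, "batch-size", 64L)),
    learning_rate = as.numeric(flag(flags, "lr", 3e-5)),
    max_len = as.integer(flag(flags, "max-len", 128L)),
    seeds = list(init = seed, shuffle = seed + 1L, dropout = seed + 2L),
    use_position_vector = is.null(flags[["no-position"]]),
    use_bilstm = is.null(flags[["no-bilstm"]]))
  vocab <- build_vocab(docs, min_count = config$min_count)
  model <- model_init(vocab, config)
  if (!is.null(flags[["vectors"]]))
    model$tables <- load_word2vec(flags[["vectors"]], model$tables, vocab)
  seqs <- encode_corpus(docs, vocab, config$max_len)
  message(sprintf("training on %d documents (seed %d, %d epochs)",
                  length(seqs), seed, config$epochs))
  model <- model_train(model, seqs)
  save_model(model, out)
  message("checkpoint written to ", out)
  0L
}

cli_predict <- function(flags) {
  check_flags(flags, c("model", "in", "out"))
  model <- load_model(flag(flags, "model", stop("--model is required")))
  docs <- read_dataset(flag(flags, "in", stop("--in is required")))
  labels <- model_predict(model, docs)
  out_df <- data.frame(id = docs$id, text = docs$text,
                       label = as.integer(labels), stringsAsFactors = FALSE)
  write_dataset(out_df, flag(flags, "out", stop("--out is required")))
  0L
}

cli_evaluate <- function(flags) {
  check_flags(flags, c("pred", "gold", "positive", "micro", "out"))
  pred <- read_dataset(flag(flags, "pred", stop("--pred is required")),
                       labelled = TRUE)
  gold <- read_dataset(flag(flags, "gold", stop("--gold is required")),
                       labelled = TRUE)
  if (!identical(pred$id, gold$id))
    stop("prediction and gold ids do not match")
  rep <- list()
  if (!is.null(flags[["micro"]])) {
    subset <- as.integer(strsplit(flags[["micro"]], ",", fixed = TRUE)[[1]])
    rep$micro_f1 <- micro_f1(gold$label, pred$label, subset)
  } else {
    pos <- as.integer(flag(flags, "positive", 1L))
    m <- precision_recall_f1(confusion(gold$label, pred$label, pos))
    rep <- round_metrics(m)
  }
  for (nm in names(rep)) cat(sprintf("%s: %.3f\n", nm, rep[[nm]]))
  out <- flag(flags, "out")
  if (!is.null(out)) {
    writeLines(sprintf("%s: %.3f", names(rep), unlist(rep)), out)
    jsonlite::write_json(rep, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  0L
}
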