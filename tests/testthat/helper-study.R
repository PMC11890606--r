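# Learning-capability / ablation studies are expensive (15 training runs);
# compute them once and share across test blocks.
.study_cache <- new.env(parent = emptyenv())

study_results <- function() {
  if (is.null(.study_cache$res)) {
    res <- list()
    for (v in c("full", "no_position", "no_bilstm")) {
      res[[v]] <- lapply(1:5, function(s) {
        r <- learning_study(seed = s, variant = v, n_docs = 2000L)
        r$model <- NULL
        r
      })
    }
    .study_cache$res <- res
  }
  .study_cache$res
}
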