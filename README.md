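# tweetformer

Classification of short, noisy social-media texts — adverse-drug-reaction
(ADR) mentions, medication intake, informative outbreak tweets — with a
two-phase **position-context additive-attention** model, implemented
entirely in R and C++ (no deep-learning framework required):

* **Phase I — representation.** Each token is the end-to-end
  concatenation of a trainable 300-d word vector and a fixed random 300-d
  positional vector (a 128-row table, one row per position), giving a
  600-d input in which the same word differs by position.
  Out-of-vocabulary words are sums of character n-gram subunit vectors.
  A two-layer bidirectional LSTM (150 units per direction) encodes
  context; its output is a learned softmax-weighted sum of the projected
  inputs and the two layer outputs.
* **Phase II — linear-complexity attention.** Sixteen additive-attention
  heads summarize queries into a global query
  `q = Σᵢ softmaxᵢ(w_qᵀqᵢ/√d_h) qᵢ`, form context-aware keys
  `pᵢ = q ⊙ kᵢ`, pool them into a global key `k`, modulate values
  `uᵢ = k ⊙ vᵢ`, and emit `Wr uᵢ + b + qᵢ`. Nothing quadratic in the
  sequence length is ever materialized. Gradients of the scoring vectors
  `w_q`, `w_k` pass through an exponentially weighted moving average
  (ρ = 0.8) before the optimizer uses them.

Training follows the benchmark recipe: 3 epochs, Adam at 3e-5 with 10%
linear warmup then linear decay, batch 64, max length 128, dropout 0.3 on
the LSTM outputs, decision threshold 0.5. The package adds the matching
tweet-normalization pipeline, word+subunit tokenizer, positive-class and
micro-averaged F1 evaluation, a seeded synthetic-corpus generator, and a
small CLI (`preprocess | synth | train | predict | evaluate`).

## Worked example

The evaluation module reproduces published error-analysis arithmetic for
a flu-vaccination tweet task — from counts tp = 802, fp = 183, fn = 99:

```r
library(tweetformer)
round_metrics(precision_recall_f1(confusion_counts(tp = 802, fp = 183, fn = 99)))
#> $precision  0.814
#> $recall     0.890
#> $f1         0.850
```

i.e. precision 0.814, recall 0.890, F1 0.850: the model found 802 of the
901 true vaccination mentions and 183 of its 985 positive calls were
wrong.

End-to-end on a synthetic ADR-style corpus (600 tweets, two classes with
disjoint marker keywords, URLs/emoji/elongations/OOV noise; 80/20 split).
From-scratch desk-scale training needs a from-scratch learning rate —
the default 3e-5 is a fine-tuning rate for pretrained representations
(see the methods vignette):

```r
r <- learning_study(seed = 42, n_docs = 600,
                    config_overrides = list(learning_rate = 3e-3))
#> held-out F1 0.901  precision 0.868  recall 0.937  AUC 0.974
#> training loss 0.6880 -> 0.0785   (train n=480, test n=120)
```

The trained classifier recovers the keyword signal: F1 0.901 against a
Bayes ceiling of ~0.95 for this signal strength (10% of documents carry
no marker and are irreducibly ambiguous).

The same flow from the shell (the launcher installs under
`$(Rscript -e 'cat(system.file("exec", "tweetformer", package = "tweetformer"))')`;
alias it or call it via `Rscript`):

```sh
tweetformer synth    --n 600 --seed 42 --out corpus.tsv
tweetformer train    --train corpus.tsv --out model.ckpt
tweetformer predict  --model model.ckpt --in corpus.tsv --out pred.tsv
tweetformer evaluate --pred pred.tsv --gold corpus.tsv
```

## Package layout

| Area | Entry points |
|---|---|
| preprocessing | `normalize_text()`, `replace_urls()`, `replace_emojis()`, `preprocess_options()` |
| tokenizer | `build_vocab()`, `segment_oov()`, `encode()`, `save_vocabulary()` |
| embedding | `init_tables()`, `word_vector()`, `embed_sequence()`, `load_word2vec()` |
| context encoder | `bilstm_layer()`, `context_encode()` |
| attention | `additive_pool()`, `head_forward()`, `encoder_forward()`, `ewma_update()`, `count_encoder_ops()` |
| model | `model_config()`, `model_init()`, `model_train()`, `model_predict()`, `save_model()` |
| evaluation | `confusion()`, `precision_recall_f1()`, `micro_f1()`, `benchmark_confusion_counts()` |
| synthetic data | `synthetic_spec()`, `generate_corpus()` |
| experiments | `learning_study()` |
| CLI / I/O | `run_command()`, `read_dataset()`, `write_dataset()` |
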