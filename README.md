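# medtagger

Character-level named-entity recognition for medical text written without
word boundaries (e.g. Chinese clinical narratives), where entity *boundaries*
are easily broken by word segmentation (急性心肌梗死 fragmenting into
急性心肌 / 梗死) and entity *categories* can depend on context alone (发烧 as
a symptom vs. part of a disease name). The package is a self-contained,
trainable implementation of a lexicon-enhanced dual-stream architecture:

- a small trainable transformer **character encoder** (`Hc`, n x d);
- a **word stream** from exhaustive dictionary matching against a domain
  lexicon, embedded (`Hw`, m x d) and pooled per character with frequency
  weights, concatenated with the character states (n x 2d);
- **dual-stream transforms + cross-stream attention**
  (`Ac = softmax(QcKw'/sqrt(d))Vw`, and symmetrically for the word stream),
  stacked into an (n+m) x d sequence;
- **multi-head self-attention** (h heads, `sqrt(d/h)` scaling);
- a **gated graph network** (GRU-style update/reset gates) over a
  character-chain + word-coverage graph with symmetrically normalised
  adjacency `D^{-1/2} A D^{-1/2}`;
- a **linear-chain CRF**: path score
  `S(X,Y) = sum_i P_i(y_i) + sum_i T[y_i, y_{i+1}]`, log-partition by the
  forward algorithm in log space, exact Viterbi decoding, NLL training.

Training runs on a built-in reverse-mode autodiff engine (base R matrices +
BLAS) with Adam; no external deep-learning framework is required. Corpus I/O
(CoNLL-style two-column BIO, JSON-lines spans, plain-text lexicons), a
reproducible synthetic-corpus generator, entity-level P/R/F1 evaluation,
k-fold cross-validation and ablation utilities are included. The methods
vignette (`vignettes/medtagger-methods.Rmd`) documents the model, the
generator and every design decision.

## Worked example

```r
library(medtagger)

cfg  <- synth_config(n_train = 800, n_dev = 100, n_test = 100, seed = 13)
lex  <- generate_lexicon(cfg)        # 40 words, 3 categories, traps + ambiguity
corp <- generate_corpus(cfg, lex)

fit <- medtagger(corp$train, lex, dev = corp$dev,
                 config  = tagger_config(d = 32, h = 2, T_rounds = 2, depth = 1),
                 trainer = trainer_config(epochs = 10, batch_size = 8,
                                          seed = 1, verbose = TRUE))
#> epoch 1  loss 20.5615  dev F1 0.0164
#> epoch 2  loss 9.4163  dev F1 0.3803
#> ...
#> epoch 7  loss 1.7793  dev F1 0.8982
#> ...
#> epoch 10  loss 1.5543  dev F1 0.8834

print(fit)
#> <medtagger> char-encoder -> dual-stream+CSA -> MHA(h=2) -> GGNN(T=2) -> CRF
#>   d=32, encoder depth=1, |labels|=7, vocab=60, lexicon=40 words
#>   trainable parameters: 26232
#>   trained 10 epoch(s); final loss 1.5543; best dev F1 0.8982

evaluate_tagger(fit, corp$test)
#> entity-level micro: P=0.8333 R=0.8929 F1=0.8621 (TP=125 FP=25 FN=15)
#>  category TP FP FN      P      R     F1
#>      cat1 34  6  3 0.8500 0.9189 0.8831
#>      cat2 46  7  2 0.8679 0.9583 0.9109
#>      cat3 45 12 10 0.7895 0.8182 0.8036

predict(fit, paste(corp$test[[1]]$chars, collapse = ""))[[1]]
#>   start end category text
#> 1    14  16     cat2   GJ
```

The printed numbers mean: per-epoch mean CRF negative log-likelihood and
entity-level micro-F1 on the dev split; the evaluation line counts a
predicted span as correct only when start, end and category all match a gold
span (`TP`), with `FP`/`FN` the unmatched predictions/gold entities and
P/R/F1 the derived rates. Predicted spans use 0-based half-open character
offsets into the input string. This is a small illustrative configuration;
the full-size benchmark model (d = 64, depth 2, 2000 training sentences)
reaches held-out F1 above 0.98 and is what the test suite trains.

A thin CLI wraps the same functions
(`simulate`/`train`/`evaluate`/`predict`/`ablate`/`crossval`):

```sh
Rscript inst/cli/medtagger.R simulate --out data/
Rscript inst/cli/medtagger.R train --train data/train.bio \
    --lexicon data/lexicon.txt --dev data/dev.bio --model model.rds
Rscript inst/cli/medtagger.R predict --model model.rds --text "..."
```

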