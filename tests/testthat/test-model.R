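tiny_data <- function(seed = 17) {
  cfg <- synth_config(n_train = 30, n_dev = 8, n_test = 8, lexicon_size = 10,
                      char_vocab_size = 30, min_len = 5, max_len = 14,
                      seed = seed)
  lex <- generate_lexicon(cfg)
  c(generate_corpus(cfg, lex), list(synth = cfg))
}

tiny_config <- function(...) tagger_config(d = 8, h = 2, T_rounds = 1,
                                           depth = 1, ...)

test_that("model assembly is seed-deterministic and counts parameters monotonically", {
  dat <- tiny_data()
  labels <- medtagger:::label_inventory(dat$train)
  vocab <- medtagger:::corpus_vocab(dat$train)

  m1 <- build_tagger(tiny_config(), dat$lexicon, labels, vocab, seed = 4)
  m2 <- build_tagger(tiny_config(), dat$lexicon, labels, vocab, seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- build_tagger(tiny_config(), dat$lexicon, labels, vocab, seed = 5)
  expect_false(identical(m1$params, m3$params))

  full <- n_params(m1)
  for (flag in c("use_dsn_csa", "use_mha", "use_ggnn")) {
    args <- stats::setNames(list(FALSE), flag)
    mv <- build_tagger(do.call(tiny_config, args), dat$lexicon, labels,
                       vocab, seed = 4)
    expect_lt(n_params(mv), full)
  }
  # everything off: CRF on (projected) fused features, the smallest variant
  m_min <- build_tagger(tiny_config(use_dsn_csa = FALSE, use_mha = FALSE,
                                    use_ggnn = FALSE),
                        dat$lexicon, labels, vocab, seed = 4)
  expect_lt(n_params(m_min), full)
})

test_that("an assembled model produces finite emissions of contract shape", {
  dat <- tiny_data()
  labels <- medtagger:::label_inventory(dat$train)
  vocab <- medtagger:::corpus_vocab(dat$train)
  m <- build_tagger(tiny_config(), dat$lexicon, labels, vocab, seed = 1)
  s <- Find(function(s) {
    medtagger:::prep_sentence(m, s$chars)$m > 0
  }, dat$train)
  expect_false(is.null(s))
  prep <- medtagger:::prep_sentence(m, s$chars, s$labels)
  P <- medtagger:::forward_emissions(m, prep)
  expect_equal(dim(P), c(s$n, length(labels)))
  expect_true(all(is.finite(P)))
})

test_that("training reduces the loss, logs history, and checkpoints round-trip", {
  dat <- tiny_data()
  tr <- trainer_config(epochs = 3, batch_size = 8, lr = 3e-3, seed = 2)
  log <- withr::local_tempfile(fileext = ".jsonl")
  tr$log_file <- log
  fit <- medtagger(dat$train, dat$lexicon, dev = dat$dev,
                   config = tiny_config(), trainer = tr)
  h <- fit$history
  expect_gte(nrow(h), 1)
  expect_true(all(is.finite(h$loss)))
  if (nrow(h) >= 3) expect_lt(h$loss[3], h$loss[1])

  # JSON-lines log mirrors the history
  recs <- lapply(readLines(log), jsonlite::fromJSON)
  expect_length(recs, nrow(h))
  expect_equal(recs[[1]]$loss, h$loss[1])

  # unknown optimiser names are rejected up front
  expect_error(trainer_config(optimizer = "sgd"), "arg")

  # checkpoint save/load reproduces the dev evaluation exactly
  f <- withr::local_tempfile(fileext = ".rds")
  save_tagger(fit, f)
  back <- load_tagger(f)
  expect_identical(back$params, fit$params)
  ev1 <- evaluate_tagger(fit, dat$dev)
  ev2 <- evaluate_tagger(back, dat$dev)
  expect_identical(ev1, ev2)

  # methods run on the fitted object
  expect_output(print(fit), "medtagger")
  expect_output(print(summary(fit, test = dat$test)), "Held-out")
  expect_named(coef(fit))
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})

test_that("same seed and configuration give identical training runs", {
  dat <- tiny_data()
  ckpt <- withr::local_tempfile(fileext = ".rds")
  tr <- trainer_config(epochs = 1, batch_size = 8, seed = 7,
                       checkpoint = ckpt)
  f1 <- medtagger(dat$train, dat$lexicon, config = tiny_config(), trainer = tr)
  f2 <- medtagger(dat$train, dat$lexicon, config = tiny_config(), trainer = tr)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history$loss, f2$history$loss)
  # the trainer-level checkpoint persists the fitted model
  expect_true(file.exists(ckpt))
  expect_identical(load_tagger(ckpt)$params, f2$params)
})

test_that("prediction yields offset-faithful spans consistent with decoded labels", {
  dat <- tiny_data()
  fit <- medtagger(dat$train, dat$lexicon, config = tiny_config(),
                   trainer = trainer_config(epochs = 1, seed = 3))
  texts <- vapply(dat$test[1:4], function(s) paste(s$chars, collapse = ""), "")
  spans <- predict(fit, texts)
  labels <- predict(fit, texts, type = "labels")
  for (i in seq_along(texts)) {
    chars <- strsplit(texts[i], "")[[1]]
    # offsets index the input exactly: the slice equals the surface form
    sp <- spans[[i]]
    for (j in seq_len(nrow(sp))) {
      expect_identical(paste(chars[(sp$start[j] + 1):sp$end[j]],
                             collapse = ""), sp$text[j])
    }
    # spans and labels are two views of the same decode
    expect_equal(spans_to_bio(length(chars),
                              sp[, c("start", "end", "category")]),
                 validate_bio(labels[[i]], repair = TRUE))
  }
  expect_error(predict(fit, ""), "empty text")
  # two evaluations of one checkpoint agree exactly
  expect_identical(evaluate_tagger(fit, dat$test), evaluate_tagger(fit, dat$test))
})

test_that("per-category evaluation rows sum to the micro totals after decoding", {
  dat <- tiny_data()
  fit <- medtagger(dat$train, dat$lexicon, config = tiny_config(),
                   trainer = trainer_config(epochs = 2, seed = 5))
  ev <- evaluate_tagger(fit, dat$test)
  expect_equal(sum(ev$by_category$TP), ev$overall$TP)
  expect_equal(sum(ev$by_category$FP), ev$overall$FP)
  expect_equal(sum(ev$by_category$FN), ev$overall$FN)
})

test_that("ablation suite reports one row per variant and seed with ordered sizes", {
  dat <- tiny_data()
  res <- run_ablation(dat$train, dat$test, dat$lexicon,
                      config = tiny_config(),
                      trainer = trainer_config(epochs = 1, seed = 1),
                      seeds = 1L)
  expect_equal(nrow(res$runs), 4)
  expect_setequal(res$runs$variant,
                  c("full", "no_dsn_csa", "no_mha", "no_ggnn"))
  full_size <- res$runs$n_params[res$runs$variant == "full"]
  for (v in c("no_dsn_csa", "no_mha", "no_ggnn")) {
    expect_lt(res$runs$n_params[res$runs$variant == v], full_size)
  }
  expect_output(print(res), "Ablation summary")
})

test_that("cross-validation partitions and scores every fold", {
  dat <- tiny_data()
  corpus <- dat$train[1:12]
  res <- crossval_tagger(corpus, dat$lexicon, k = 2,
                         config = tiny_config(),
                         trainer = trainer_config(epochs = 1, seed = 1),
                         seed = 3)
  expect_equal(nrow(res), 2)
  expect_true(all(res$F1 >= 0 & res$F1 <= 1))
  expect_true(is.finite(attr(res, "summary")$mean_F1))
})

test_that("training aborts with a diagnostic on divergence", {
  dat <- tiny_data()
  # absurd learning rate with no clipping forces non-finite loss quickly
  tr <- trainer_config(epochs = 5, lr = 1e150, clip = Inf, seed = 1)
  expect_error(
    medtagger(dat$train, dat$lexicon, config = tiny_config(), trainer = tr),
    "diverged")
  expect_error(medtagger(list(), dat$lexicon), "empty training corpus")
})
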