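# The training engine's gradients are pinned against central finite
# differences, both per primitive and through the full assembled model.

num_grad <- function(fn, params, name, i, j, eps = 1e-6) {
  p <- params
  p[[name]][i, j] <- p[[name]][i, j] + eps
  up <- fn(p)
  p[[name]][i, j] <- p[[name]][i, j] - 2 * eps
  dn <- fn(p)
  (up - dn) / (2 * eps)
}

test_that("primitive operations backpropagate exact gradients", {
  set.seed(1)
  params <- list(A = matrix(rnorm(6), 2, 3), B = matrix(rnorm(12), 3, 4),
                 b = matrix(rnorm(4), 1, 4), E = matrix(rnorm(20), 5, 4))
  idx <- c(2L, 2L, 4L)  # repeated rows exercise scatter-add
  loss_fn <- function(p) {
    tp <- medtagger:::ad_tape(p)
    a <- medtagger:::ad_param(tp, "A")
    bm <- medtagger:::ad_param(tp, "B")
    x <- medtagger:::ad_matmul(tp, a, bm)                      # 2x4
    x <- medtagger:::ad_add_bias(tp, x, medtagger:::ad_param(tp, "b"))
    x <- medtagger:::ad_tanh(tp, x)
    e <- medtagger:::ad_embed(tp, "E", idx)                    # 3x4
    y <- medtagger:::ad_matmul_nt(tp, x, e)                    # 2x3
    y <- medtagger:::ad_softmax_rows(tp, y)
    z <- medtagger:::ad_mul(tp, y, medtagger:::ad_one_minus(tp, y))
    z <- medtagger:::ad_sigmoid(tp, medtagger:::ad_scale(tp, z, 3))
    stacked <- medtagger:::ad_rbind(tp, z, z)                  # 4x3
    sliced <- medtagger:::ad_rows(tp, stacked, c(1L, 3L, 3L))
    wide <- medtagger:::ad_cbind(tp, sliced, sliced)           # 3x6
    # scalar loss: sum of squares via elementwise product against itself
    sq <- medtagger:::ad_mul(tp, wide, wide)
    ones_r <- medtagger:::ad_const(tp, matrix(1, 1, 3))
    ones_c <- medtagger:::ad_const(tp, matrix(1, 6, 1))
    s <- medtagger:::ad_matmul(tp, medtagger:::ad_matmul(tp, ones_r, sq),
                               ones_c)
    list(tp = tp, node = s)
  }
  run <- loss_fn(params)
  medtagger:::ad_backward(run$tp, run$node)
  g <- as.list(run$tp$pgrads)
  val_fn <- function(p) {
    r <- loss_fn(p)
    medtagger:::ad_val(r$tp, r$node)[1, 1]
  }
  for (nm in names(params)) {
    expect_false(is.null(g[[nm]]), info = nm)
    for (probe in 1:3) {
      i <- sample(nrow(params[[nm]]), 1)
      j <- sample(ncol(params[[nm]]), 1)
      if (nm == "E") i <- sample(unique(idx), 1)  # untouched rows have grad 0
      expect_equal(g[[nm]][i, j], num_grad(val_fn, params, nm, i, j),
                   tolerance = 1e-4, info = paste(nm, i, j))
    }
  }
  # embedding rows never gathered receive zero gradient
  expect_equal(g$E[1, ], rep(0, 4))
})

make_tiny_fit_env <- function(config, seed = 3) {
  cfg <- synth_config(n_train = 12, n_dev = 4, n_test = 4, lexicon_size = 8,
                      char_vocab_size = 30, min_len = 5, max_len = 12,
                      seed = 17)
  lex <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, lex)
  model <- build_tagger(config, lex,
                        medtagger:::label_inventory(corp$train),
                        medtagger:::corpus_vocab(corp$train), seed = seed)
  sent <- NULL
  for (s in corp$train) {   # pick a sentence with at least one lexicon match
    p <- medtagger:::prep_sentence(model, s$chars, s$labels)
    if (p$m > 0) { sent <- p; break }
  }
  list(model = model, prep = sent, corp = corp, lex = lex, synth = cfg)
}

test_that("full-model tape gradients match finite differences (all blocks on)", {
  config <- tagger_config(d = 8, h = 2, T_rounds = 2, depth = 1)
  env <- make_tiny_fit_env(config)
  expect_false(is.null(env$prep))
  tp <- medtagger:::ad_tape(env$model$params)
  node <- medtagger:::tape_nll(tp, config, env$prep)
  medtagger:::ad_backward(tp, node)
  g <- as.list(tp$pgrads)
  val_fn <- function(p) {
    t2 <- medtagger:::ad_tape(p)
    n2 <- medtagger:::tape_nll(t2, config, env$prep)
    medtagger:::ad_val(t2, n2)[1, 1]
  }
  set.seed(8)
  for (nm in c("E_char", "enc1.Wv", "dsn.Wc", "csa.Wk", "mha1.Wq", "mha.Wo",
               "ggnn.Wg", "ggnn.Ur", "crf.W", "crf.T")) {
    probe <- which(abs(g[[nm]]) == max(abs(g[[nm]])), arr.ind = TRUE)[1, ]
    a <- g[[nm]][probe[1], probe[2]]
    b <- num_grad(val_fn, env$model$params, nm, probe[1], probe[2])
    expect_equal(a, b, tolerance = 1e-3, info = nm)
  }
})

test_that("training forward equals the composed module forward, per ablation variant", {
  variants <- list(
    tagger_config(d = 8, h = 2, T_rounds = 2, depth = 1),
    tagger_config(d = 8, h = 2, T_rounds = 2, depth = 1, use_dsn_csa = FALSE),
    tagger_config(d = 8, h = 2, T_rounds = 2, depth = 1, use_mha = FALSE),
    tagger_config(d = 8, h = 2, T_rounds = 2, depth = 1, use_ggnn = FALSE),
    tagger_config(d = 8, h = 2, T_rounds = 1, depth = 1, word_attn_char_queries = TRUE),
    tagger_config(d = 8, h = 2, T_rounds = 1, depth = 1, csa_residual = FALSE),
    tagger_config(d = 8, h = 2, T_rounds = 1, depth = 1, residual = TRUE),
    tagger_config(d = 8, h = 2, T_rounds = 1, depth = 1,
                  share_projections = FALSE))
  for (config in variants) {
    env <- make_tiny_fit_env(config)
    expect_false(is.null(env$prep))
    P_plain <- medtagger:::forward_emissions(env$model, env$prep)
    tp <- medtagger:::ad_tape(env$model$params)
    node <- medtagger:::tape_nll(tp, config, env$prep)
    nll_tape <- medtagger:::ad_val(tp, node)[1, 1]
    nll_plain <- crf_nll(P_plain, env$model$params$crf.T, env$prep$gold)
    expect_equal(nll_tape, nll_plain, tolerance = 1e-10)
  }
})

test_that("the tape handles sentences with no lexicon match (word fallback)", {
  config <- tagger_config(d = 8, h = 2, T_rounds = 1, depth = 1)
  env <- make_tiny_fit_env(config)
  model <- env$model
  # filler characters never occur in lexicon words, so no match is possible
  chars <- rep(medtagger:::synth_pools(env$synth)$filler[1], 6)
  prep <- medtagger:::prep_sentence(model, chars, rep("O", 6))
  expect_equal(prep$m, 0L)
  P <- medtagger:::forward_emissions(model, prep)
  expect_equal(dim(P), c(6L, length(model$labels)))
  tp <- medtagger:::ad_tape(model$params)
  node <- medtagger:::tape_nll(tp, config, prep)
  expect_equal(medtagger:::ad_val(tp, node)[1, 1],
               crf_nll(P, model$params$crf.T, prep$gold), tolerance = 1e-10)
  medtagger:::ad_backward(tp, node)
  expect_true(is.null(tp$pgrads$E_word) ||
                all(as.list(tp$pgrads)$E_word == 0))
})
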