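# Full tagger: assembly of the character encoder, lexicon word stream,
# dual-stream + cross-stream attention, multi-head attention, gated graph
# propagation and CRF decoding, plus the training engine (reverse-mode
# autodiff + Adam) and the classic fit/predict/summary interface.

#' Model architecture configuration
#'
#' Ablation flags compose into valid architectures: disabling the dual
#' stream + cross-stream attention routes the fused character-word features
#' through a learned input projection straight to multi-head attention;
#' disabling MHA routes the cross-stream output directly into the graph
#' network; disabling the graph network feeds the attention output to the
#' emission layer.
#'
#' @param d hidden dimension (even, divisible by `h`).
#' @param h number of attention heads.
#' @param T_rounds graph propagation rounds.
#' @param depth character-encoder blocks.
#' @param max_word_len longest lexicon match considered.
#' @param use_dsn_csa,use_mha,use_ggnn ablation switches.
#' @param word_attn_char_queries compute the word-side cross-attention from
#'   character queries (see [cross_stream_attention()]); the word-side rows
#'   are then graph-linked one-to-one to their characters.
#' @param csa_residual per-stream residual connections around the
#'   cross-stream attention; on by default because the pure attention output
#'   collapses the character stream to at most m distinct rows (see the
#'   methods vignette).
#' @param residual add the attention output back onto the graph output.
#' @param word_word_edges connect overlapping word nodes in the graph.
#' @param share_projections share cross-stream Q/K/V across streams.
#' @return list of class `tagger_config`.
#' @export
tagger_config <- function(d = 64L, h = 2L, T_rounds = 2L, depth = 2L,
                          max_word_len = 8L, use_dsn_csa = TRUE,
                          use_mha = TRUE, use_ggnn = TRUE,
                          word_attn_char_queries = FALSE, csa_residual = TRUE,
                          residual = FALSE,
                          word_word_edges = FALSE,
                          share_projections = TRUE) {
  if (d %% 2 != 0) stop("d must be even")
  if (use_mha && d %% h != 0) stop("d must be divisible by h")
  structure(list(d = as.integer(d), h = as.integer(h),
                 T_rounds = as.integer(T_rounds), depth = as.integer(depth),
                 max_word_len = as.integer(max_word_len),
                 use_dsn_csa = isTRUE(use_dsn_csa),
                 use_mha = isTRUE(use_mha), use_ggnn = isTRUE(use_ggnn),
                 word_attn_char_queries = isTRUE(word_attn_char_queries),
                 csa_residual = isTRUE(csa_residual),
                 residual = isTRUE(residual),
                 word_word_edges = isTRUE(word_word_edges),
                 share_projections = isTRUE(share_projections)),
            class = "tagger_config")
}

#' Training configuration
#'
#' @param epochs maximum training epochs.
#' @param batch_size sentences per gradient step (gradients are accumulated
#'   per sentence within the batch).
#' @param optimizer optimiser name; `"adam"` is the only implemented one.
#' @param lr Adam learning rate.
#' @param clip global gradient-norm clip.
#' @param patience early-stopping patience on dev F1 (epochs).
#' @param stop_f1 stop as soon as dev F1 reaches this value.
#' @param seed RNG seed for initialisation and shuffling.
#' @param verbose print per-epoch progress.
#' @param log_file optional JSON-lines file receiving per-epoch records.
#' @param checkpoint optional path: the fitted (best-dev) model is saved
#'   there via [save_tagger()] when training finishes.
#' @return list of class `trainer_config`.
#' @export
trainer_config <- function(epochs = 10L, batch_size = 16L,
                           optimizer = "adam", lr = 1e-3,
                           clip = 5, patience = 3L, stop_f1 = 0.999,
                           seed = 1L, verbose = FALSE, log_file = NULL,
                           checkpoint = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  optimizer <- match.arg(optimizer)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 lr = lr, clip = clip,
                 patience = as.integer(patience), stop_f1 = stop_f1,
                 seed = as.integer(seed), verbose = isTRUE(verbose),
                 log_file = log_file, checkpoint = checkpoint),
            class = "trainer_config")
}

# ---- parameter initialisation --------------------------------------------

# Flat named list of trainable matrices; biases are 1 x k matrices. A single
# seed fixes every draw, so identical seed + config give identical
# parameters.
init_tagger_params <- function(cfg, vocab_size, lexicon_size, n_labels,
                               seed = 1L) {
  set.seed(seed)
  d <- cfg$d
  p <- list(E_char = init_mat(vocab_size, d))
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("enc", l, ".")
    p[[paste0(pre, "Wq")]] <- init_mat(d, d)
    p[[paste0(pre, "Wk")]] <- init_mat(d, d)
    p[[paste0(pre, "Wv")]] <- init_mat(d, d)
    p[[paste0(pre, "W1")]] <- init_mat(d, d)
    p[[paste0(pre, "b1")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "W2")]] <- init_mat(d, d)
    p[[paste0(pre, "b2")]] <- matrix(0, 1L, d)
  }
  p$E_word <- if (lexicon_size > 0) init_mat(lexicon_size, d) else
    matrix(0, 0L, d)
  if (cfg$use_dsn_csa) {
    p$dsn.Wc <- init_mat(2L * d, d); p$dsn.bc <- matrix(0, 1L, d)
    p$dsn.Ww <- init_mat(d, d); p$dsn.bw <- matrix(0, 1L, d)
    p$csa.Wq <- init_mat(d, d); p$csa.Wk <- init_mat(d, d)
    p$csa.Wv <- init_mat(d, d)
    if (!cfg$share_projections) {
      p$csa.Wq_w <- init_mat(d, d); p$csa.Wk_w <- init_mat(d, d)
      p$csa.Wv_w <- init_mat(d, d)
    }
  } else {
    p$proj.W <- init_mat(2L * d, d); p$proj.b <- matrix(0, 1L, d)
  }
  if (cfg$use_mha) {
    dh <- d %/% cfg$h
    for (i in seq_len(cfg$h)) {
      pre <- paste0("mha", i, ".")
      p[[paste0(pre, "Wq")]] <- init_mat(d, dh)
      p[[paste0(pre, "Wk")]] <- init_mat(d, dh)
      p[[paste0(pre, "Wv")]] <- init_mat(d, dh)
    }
    p$mha.Wo <- init_mat(d, d)
  }
  if (cfg$use_ggnn) {
    for (nm in c("Wg", "Wz", "Uz", "Wr", "Ur", "Wh", "Uh")) {
      p[[paste0("ggnn.", nm)]] <- init_mat(d, d)
    }
    for (nm in c("bz", "br", "bh")) {
      p[[paste0("ggnn.", nm)]] <- matrix(0, 1L, d)
    }
  }
  p$crf.W <- init_mat(d, n_labels)
  p$crf.b <- matrix(0, 1L, n_labels)
  p$crf.T <- matrix(stats::runif(n_labels^2, -0.1, 0.1), n_labels, n_labels)
  p
}

# ---- module views over the flat parameter list ---------------------------

encoder_view <- function(model) {
  p <- model$params
  blocks <- lapply(seq_len(model$config$depth), function(l) {
    pre <- paste0("enc", l, ".")
    list(Wq = p[[paste0(pre, "Wq")]], Wk = p[[paste0(pre, "Wk")]],
         Wv = p[[paste0(pre, "Wv")]], W1 = p[[paste0(pre, "W1")]],
         b1 = p[[paste0(pre, "b1")]], W2 = p[[paste0(pre, "W2")]],
         b2 = p[[paste0(pre, "b2")]])
  })
  structure(list(vocab = model$vocab, d = model$config$d,
                 depth = model$config$depth, E = p$E_char, blocks = blocks),
            class = "char_encoder_params")
}

stream_view <- function(model) {
  p <- model$params
  sp <- list(d = model$config$d, Wc = p$dsn.Wc, bc = p$dsn.bc,
             Ww = p$dsn.Ww, bw = p$dsn.bw, Wq = p$csa.Wq, Wk = p$csa.Wk,
             Wv = p$csa.Wv,
             share_projections = model$config$share_projections)
  if (!model$config$share_projections) {
    sp$Wq_w <- p$csa.Wq_w; sp$Wk_w <- p$csa.Wk_w; sp$Wv_w <- p$csa.Wv_w
  }
  structure(sp, class = "stream_params")
}

mha_view <- function(model) {
  p <- model$params
  cfg <- model$config
  heads <- lapply(seq_len(cfg$h), function(i) {
    pre <- paste0("mha", i, ".")
    list(Wq = p[[paste0(pre, "Wq")]], Wk = p[[paste0(pre, "Wk")]],
         Wv = p[[paste0(pre, "Wv")]])
  })
  structure(list(d = cfg$d, h = cfg$h, d_head = cfg$d %/% cfg$h,
                 heads = heads, Wo = p$mha.Wo),
            class = "mha_params")
}

ggnn_view <- function(model) {
  p <- model$params
  structure(list(d = model$config$d, T_rounds = model$config$T_rounds,
                 Wg = p$ggnn.Wg, Wz = p$ggnn.Wz, Uz = p$ggnn.Uz,
                 Wr = p$ggnn.Wr, Ur = p$ggnn.Ur, Wh = p$ggnn.Wh,
                 Uh = p$ggnn.Uh, bz = p$ggnn.bz, br = p$ggnn.br,
                 bh = p$ggnn.bh),
            class = "ggnn_params")
}

crf_view <- function(model) {
  p <- model$params
  structure(list(labels = model$labels, T_mat = p$crf.T, W_emit = p$crf.W,
                 b_emit = as.vector(p$crf.b), start = NULL, stop = NULL),
            class = "crf_params")
}

# ---- sentence preparation (deterministic, cacheable) ---------------------

prep_sentence <- function(model, chars, labels = NULL) {
  cfg <- model$config
  n <- length(chars)
  wf <- match_lexicon(chars, model$lexicon, cfg$max_word_len)
  m <- wf$m
  M <- if (m > 0) word_pooling_matrix(n, wf$matches) else NULL
  # graph coverage: word nodes only exist downstream of the dual stream; in
  # literal cross-attention mode the word-side output has one row per
  # character, each tied to its character node.
  cov <- list()
  if (cfg$use_dsn_csa && m > 0) {
    cov <- if (cfg$word_attn_char_queries) {
      as.list(seq_len(n))
    } else {
      lapply(seq_len(m), function(j) {
        (wf$matches$start[j] + 1L):wf$matches$end[j]
      })
    }
  }
  A_norm <- NULL
  if (cfg$use_ggnn) {
    A_norm <- normalize_adjacency(
      graph_from_coverage(n, cov, cfg$word_word_edges))
  }
  gold <- NULL
  if (!is.null(labels)) {
    gold <- match(labels, model$labels)
    if (anyNA(gold)) {
      stop("label(s) not in the model inventory: ",
           paste(unique(labels[is.na(gold)]), collapse = ", "))
    }
  }
  list(chars = chars, n = n,
       char_idx = char_indices(chars, model$vocab),
       pe = positional_encoding(n, cfg$d),
       wf = wf, m = m, M = M, A_norm = A_norm, gold = gold)
}

# ---- plain (inference) forward, composed from the module functions -------

forward_emissions <- function(model, prep, details = FALSE) {
  cfg <- model$config
  d <- cfg$d
  n <- prep$n
  Hc <- encode_characters(prep$chars, encoder_view(model))
  Hw <- model$params$E_word[prep$wf$matches$lex_index, , drop = FALSE]
  pooled <- if (prep$m > 0) prep$M %*% Hw else matrix(0, n, d)
  fused <- fuse_char_word(Hc, pooled)
  if (cfg$use_dsn_csa) {
    sp <- stream_view(model)
    ts <- transform_streams(fused, Hw, sp)
    cs <- cross_stream_attention(ts$Hc_prime, ts$Hw_prime, sp,
                                 word_attn_char_queries =
                                   cfg$word_attn_char_queries,
                                 residual = cfg$csa_residual)
    Hp <- cs$H_prime
  } else {
    Hp <- tanh(sweep(fused %*% model$params$proj.W, 2L,
                     model$params$proj.b, "+"))
  }
  Hpp <- if (cfg$use_mha) multi_head_attention(Hp, mha_view(model)) else Hp
  if (cfg$use_ggnn) {
    Hg <- ggnn_propagate(Hpp, list(A_norm = prep$A_norm), ggnn_view(model))
    Hfinal <- if (cfg$residual) Hpp + Hg else Hg
  } else {
    Hfinal <- Hpp
  }
  P <- emission_scores(Hfinal[seq_len(n), , drop = FALSE], crf_view(model))
  if (details) list(P = P, Hc = Hc, fused = fused, Hfinal = Hfinal) else P
}

# ---- autodiff forward (training) -----------------------------------------

# Builds the tape for one sentence and returns the index of the NLL node.
tape_nll <- function(tp, cfg, prep) {
  d <- cfg$d
  n <- prep$n
  h <- ad_embed(tp, "E_char", prep$char_idx)
  h <- ad_add(tp, h, ad_const(tp, prep$pe))
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("enc", l, ".")
    q <- ad_matmul(tp, h, ad_param(tp, paste0(pre, "Wq")))
    k <- ad_matmul(tp, h, ad_param(tp, paste0(pre, "Wk")))
    v <- ad_matmul(tp, h, ad_param(tp, paste0(pre, "Wv")))
    a <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul_nt(tp, q, k), 1 / sqrt(d)))
    h <- ad_add(tp, h, ad_matmul(tp, a, v))
    f1 <- ad_tanh(tp, ad_add_bias(tp,
                                  ad_matmul(tp, h, ad_param(tp, paste0(pre, "W1"))),
                                  ad_param(tp, paste0(pre, "b1"))))
    h <- ad_add(tp, h, ad_add_bias(tp,
                                   ad_matmul(tp, f1, ad_param(tp, paste0(pre, "W2"))),
                                   ad_param(tp, paste0(pre, "b2"))))
  }
  hw <- NULL
  if (prep$m > 0) {
    hw <- ad_embed(tp, "E_word", prep$wf$matches$lex_index)
    pooled <- ad_matmul(tp, ad_const(tp, prep$M), hw)
  } else {
    pooled <- ad_const(tp, matrix(0, n, d))
  }
  fused <- ad_cbind(tp, h, pooled)
  if (cfg$use_dsn_csa) {
    hcp <- ad_tanh(tp, ad_add_bias(tp,
                                   ad_matmul(tp, fused, ad_param(tp, "dsn.Wc")),
                                   ad_param(tp, "dsn.bc")))
    if (prep$m > 0) {
      hwp <- ad_tanh(tp, ad_add_bias(tp,
                                     ad_matmul(tp, hw, ad_param(tp, "dsn.Ww")),
                                     ad_param(tp, "dsn.bw")))
      qw_name <- if (cfg$share_projections) "csa.Wq" else "csa.Wq_w"
      kw_name <- if (cfg$share_projections) "csa.Wk" else "csa.Wk_w"
      vw_name <- if (cfg$share_projections) "csa.Wv" else "csa.Wv_w"
      qc <- ad_matmul(tp, hcp, ad_param(tp, "csa.Wq"))
      kc <- ad_matmul(tp, hcp, ad_param(tp, "csa.Wk"))
      vc <- ad_matmul(tp, hcp, ad_param(tp, "csa.Wv"))
      qw <- ad_matmul(tp, hwp, ad_param(tp, qw_name))
      kw <- ad_matmul(tp, hwp, ad_param(tp, kw_name))
      vw <- ad_matmul(tp, hwp, ad_param(tp, vw_name))
      ac <- ad_matmul(tp, ad_softmax_rows(tp,
                                          ad_scale(tp, ad_matmul_nt(tp, qc, kw), 1 / sqrt(d))), vw)
      q_word <- if (cfg$word_attn_char_queries) qc else qw
      aw <- ad_matmul(tp, ad_softmax_rows(tp,
                                          ad_scale(tp, ad_matmul_nt(tp, q_word, kc), 1 / sqrt(d))), vc)
      if (cfg$csa_residual) {
        ac <- ad_add(tp, hcp, ac)
        if (!cfg$word_attn_char_queries) aw <- ad_add(tp, hwp, aw)
      }
      hp <- ad_rbind(tp, ac, aw)
    } else {
      hp <- hcp
    }
  } else {
    hp <- ad_tanh(tp, ad_add_bias(tp,
                                  ad_matmul(tp, fused, ad_param(tp, "proj.W")),
                                  ad_param(tp, "proj.b")))
  }
  if (cfg$use_mha) {
    dh <- d %/% cfg$h
    outs <- NULL
    for (i in seq_len(cfg$h)) {
      pre <- paste0("mha", i, ".")
      q <- ad_matmul(tp, hp, ad_param(tp, paste0(pre, "Wq")))
      k <- ad_matmul(tp, hp, ad_param(tp, paste0(pre, "Wk")))
      v <- ad_matmul(tp, hp, ad_param(tp, paste0(pre, "Wv")))
      a <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul_nt(tp, q, k),
                                        1 / sqrt(dh)))
      o <- ad_matmul(tp, a, v)
      outs <- if (is.null(outs)) o else ad_cbind(tp, outs, o)
    }
    hpp <- ad_matmul(tp, outs, ad_param(tp, "mha.Wo"))
  } else {
    hpp <- hp
  }
  if (cfg$use_ggnn) {
    anorm <- ad_const(tp, prep$A_norm)
    hh <- hpp
    for (t in seq_len(cfg$T_rounds)) {
      ht <- ad_matmul(tp, ad_matmul(tp, anorm, hh),
                      ad_param(tp, "ggnn.Wg"))
      z <- ad_sigmoid(tp, ad_add_bias(tp,
                                      ad_add(tp, ad_matmul(tp, ht, ad_param(tp, "ggnn.Wz")),
                                             ad_matmul(tp, hh, ad_param(tp, "ggnn.Uz"))),
                                      ad_param(tp, "ggnn.bz")))
      r <- ad_sigmoid(tp, ad_add_bias(tp,
                                      ad_add(tp, ad_matmul(tp, ht, ad_param(tp, "ggnn.Wr")),
                                             ad_matmul(tp, hh, ad_param(tp, "ggnn.Ur"))),
                                      ad_param(tp, "ggnn.br")))
      cand <- ad_tanh(tp, ad_add_bias(tp,
                                      ad_add(tp, ad_matmul(tp, ht, ad_param(tp, "ggnn.Wh")),
                                             ad_matmul(tp, ad_mul(tp, r, hh),
                                                       ad_param(tp, "ggnn.Uh"))),
                                      ad_param(tp, "ggnn.bh")))
      hh <- ad_add(tp, ad_mul(tp, ad_one_minus(tp, z), hh),
                   ad_mul(tp, z, cand))
    }
    hfinal <- if (cfg$residual) ad_add(tp, hpp, hh) else hh
  } else {
    hfinal <- hpp
  }
  pchar <- if (nrow(ad_val(tp, hfinal)) > n) {
    ad_rows(tp, hfinal, seq_len(n))
  } else {
    hfinal
  }
  p <- ad_add_bias(tp, ad_matmul(tp, pchar, ad_param(tp, "crf.W")),
                   ad_param(tp, "crf.b"))
  ad_crf_nll(tp, p, "crf.T", prep$gold)
}

# ---- optimiser ------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- model assembly -------------------------------------------------------

#' Assemble an untrained tagger
#'
#' Builds the full model (or an ablation variant) with freshly initialised
#' parameters. The same seed and configuration always give bit-identical
#' parameters.
#'
#' @param config a [tagger_config()].
#' @param lex a [lexicon()] used for word matching and word embeddings.
#' @param labels BIO label inventory (character vector, `"O"` first by
#'   convention).
#' @param vocab character vocabulary; `"<unk>"` is appended if absent.
#' @param seed initialisation seed.
#' @return object of class `medtagger` (untrained: empty history).
#' @export
build_tagger <- function(config, lex, labels, vocab, seed = 1L) {
  if (!"<unk>" %in% vocab) vocab <- c(vocab, "<unk>")
  params <- init_tagger_params(config, length(vocab), nrow(lex),
                               length(labels), seed = seed)
  structure(list(config = config, params = params, vocab = vocab,
                 labels = labels, lexicon = lex, seed = as.integer(seed),
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      dev_f1 = numeric()),
                 best = NULL, call = NULL),
            class = "medtagger")
}

#' Number of trainable parameters
#'
#' @param object a `medtagger` model.
#' @return integer count of scalar parameters.
#' @export
n_params <- function(object) {
  sum(vapply(object$params, length, 0L))
}

label_inventory <- function(corpus) {
  cats <- sort(unique(unlist(lapply(corpus, function(s) {
    sp <- bio_to_spans(s$labels)
    sp$category
  }))))
  c("O", as.vector(rbind(paste0("B-", cats), paste0("I-", cats))))
}

corpus_vocab <- function(corpus) {
  sort(unique(unlist(lapply(corpus, `[[`, "chars"))))
}

# ---- fitting ---------------------------------------------------------------

#' Fit the lexicon-enhanced neural tagger
#'
#' Trains the full architecture (character encoder -> lexicon word stream ->
#' dual-stream cross attention -> multi-head attention -> gated graph
#' propagation -> CRF) by minimising the mean CRF negative log-likelihood
#' with Adam. Gradients come from the package's reverse-mode autodiff engine;
#' sentences are processed individually and gradients accumulated within
#' each mini-batch.
#'
#' @param x training corpus: list of [labeled_sequence()] objects.
#' @param lex a [lexicon()] of domain words.
#' @param dev optional development corpus for early stopping / model
#'   selection (entity-level micro-F1); without it the final epoch's
#'   parameters are kept.
#' @param config a [tagger_config()].
#' @param trainer a [trainer_config()].
#' @return fitted object of class `medtagger`, with `history` (per-epoch
#'   loss and dev F1) and the best-dev parameters installed.
#' @export
medtagger <- function(x, lex, dev = NULL, config = tagger_config(),
                      trainer = trainer_config()) {
  if (!length(x)) stop("empty training corpus")
  cl <- match.call()
  vocab <- corpus_vocab(x)
  labels <- label_inventory(x)
  model <- build_tagger(config, lex, labels, vocab, seed = trainer$seed)
  model$call <- cl
  preps <- lapply(x, function(s) prep_sentence(model, s$chars, s$labels))
  state <- adam_state(model$params)
  set.seed(trainer$seed + 1L)
  best_f1 <- -Inf
  best_params <- model$params
  stall <- 0L
  history <- list()
  for (epoch in seq_len(trainer$epochs)) {
    ord <- sample.int(length(preps))
    total_loss <- 0
    for (b0 in seq(1L, length(ord), by = trainer$batch_size)) {
      batch <- ord[b0:min(b0 + trainer$batch_size - 1L, length(ord))]
      pg <- new.env(parent = emptyenv())
      for (si in batch) {
        tp <- ad_tape(model$params)
        tp$pgrads <- pg
        nll <- tape_nll(tp, config, preps[[si]])
        loss_val <- ad_val(tp, nll)[1L, 1L]
        if (!is.finite(loss_val)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", sentence ", si)
        }
        total_loss <- total_loss + loss_val
        ad_backward(tp, nll)
      }
      grads <- as.list(pg)
      scale <- 1 / length(batch)
      gnorm2 <- 0
      for (nm in names(grads)) {
        grads[[nm]] <- grads[[nm]] * scale
        gnorm2 <- gnorm2 + sum(grads[[nm]]^2)
      }
      gnorm <- sqrt(gnorm2)
      if (is.finite(trainer$clip) && gnorm > trainer$clip) {
        for (nm in names(grads)) {
          grads[[nm]] <- grads[[nm]] * (trainer$clip / gnorm)
        }
      }
      upd <- adam_step(model$params, grads, state, trainer$lr)
      model$params <- upd$params
      state <- upd$state
    }
    mean_loss <- total_loss / length(preps)
    dev_f1 <- NA_real_
    if (!is.null(dev)) {
      dev_f1 <- evaluate_tagger(model, dev)$overall$F1
      if (dev_f1 > best_f1) {
        best_f1 <- dev_f1
        best_params <- model$params
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    rec <- list(epoch = epoch, loss = mean_loss, dev_f1 = dev_f1)
    history[[epoch]] <- rec
    if (!is.null(trainer$log_file)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = trainer$log_file, append = TRUE, sep = "")
    }
    if (trainer$verbose) {
      cat(sprintf("epoch %d  loss %.4f  dev F1 %s\n", epoch, mean_loss,
                  ifelse(is.na(dev_f1), "-", sprintf("%.4f", dev_f1))))
    }
    if (!is.null(dev) &&
        (dev_f1 >= trainer$stop_f1 || stall > trainer$patience)) break
  }
  if (!is.null(dev)) model$params <- best_params
  model$best <- if (is.null(dev)) NULL else list(dev_f1 = best_f1)
  model$history <- do.call(rbind, lapply(history, as.data.frame))
  model$trainer <- trainer
  if (!is.null(trainer$checkpoint)) save_tagger(model, trainer$checkpoint)
  model
}

# ---- inference -------------------------------------------------------------

decode_chars <- function(model, chars) {
  prep <- prep_sentence(model, chars)
  P <- forward_emissions(model, prep)
  vit <- viterbi_decode(P, model$params$crf.T)
  labels <- model$labels[vit$path]
  list(labels = labels, score = vit$score,
       spans = bio_to_spans(labels, repair = TRUE))
}

#' Predict entities
#'
#' Runs the deterministic forward pass and Viterbi decoding on new text.
#'
#' @param object a fitted `medtagger`.
#' @param newdata a character vector of texts (split per character), or a
#'   list of [labeled_sequence()] objects.
#' @param type `"spans"` (default) returns one span data.frame per input,
#'   with a `text` column holding the surface form; `"labels"` returns BIO
#'   label vectors.
#' @param ... unused.
#' @return list, one element per input sentence.
#' @export
predict.medtagger <- function(object, newdata, type = c("spans", "labels"),
                              ...) {
  type <- match.arg(type)
  items <- if (is.character(newdata)) {
    if (any(!nzchar(newdata))) stop("empty text")
    lapply(newdata, function(t) strsplit(t, "")[[1]])
  } else {
    lapply(newdata, function(s) {
      if (inherits(s, "labeled_sequence")) s$chars else as.character(s)
    })
  }
  lapply(items, function(chars) {
    dec <- decode_chars(object, chars)
    if (type == "labels") return(dec$labels)
    sp <- dec$spans
    sp$text <- vapply(seq_len(nrow(sp)), function(i) {
      paste(chars[(sp$start[i] + 1L):sp$end[i]], collapse = "")
    }, "")
    sp
  })
}

#' Evaluate a tagger on a labeled corpus
#'
#' Viterbi-decodes every sentence and scores the predicted spans against the
#' gold spans with strict entity-level matching.
#'
#' @param model a fitted `medtagger`.
#' @param corpus list of [labeled_sequence()] objects.
#' @return an `entity_eval` object (see [evaluate_entities()]).
#' @export
evaluate_tagger <- function(model, corpus) {
  gold <- lapply(corpus, function(s) bio_to_spans(s$labels))
  pred <- lapply(corpus, function(s) decode_chars(model, s$chars)$spans)
  evaluate_entities(gold, pred)
}

# ---- persistence -----------------------------------------------------------

#' Save / load a tagger checkpoint
#'
#' The checkpoint is a single serialised archive holding the parameters,
#' label inventory, vocabulary, configuration, training history and a hash
#' of the lexicon (to detect mismatched lexicons on reload).
#'
#' @param model a `medtagger`.
#' @param path file path.
#' @return `save_tagger` returns `path` invisibly; `load_tagger` the model.
#' @export
save_tagger <- function(model, path) {
  obj <- unclass(model)
  obj$lexicon_hash <- lexicon_hash(model$lexicon)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$lexicon_hash, lexicon_hash(obj$lexicon))) {
    stop("checkpoint lexicon hash mismatch")
  }
  obj$lexicon_hash <- NULL
  structure(obj, class = "medtagger")
}

lexicon_hash <- function(lex) {
  paste(nrow(lex), sum(utf8ToInt(paste(lex$word, collapse = ""))),
        sum(lex$frequency))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.medtagger <- function(x, ...) {
  cfg <- x$config
  blocks <- c("char-encoder",
              if (cfg$use_dsn_csa) "dual-stream+CSA" else "input-projection",
              if (cfg$use_mha) sprintf("MHA(h=%d)", cfg$h),
              if (cfg$use_ggnn) sprintf("GGNN(T=%d)", cfg$T_rounds), "CRF")
  cat("<medtagger> ", paste(blocks, collapse = " -> "), "\n", sep = "")
  cat(sprintf("  d=%d, encoder depth=%d, |labels|=%d, vocab=%d, lexicon=%d words\n",
              cfg$d, cfg$depth, length(x$labels), length(x$vocab),
              nrow(x$lexicon)))
  cat("  trainable parameters:", n_params(x), "\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s); final loss %.4f", last$epoch,
                last$loss))
    if (!is.null(x$best)) cat(sprintf("; best dev F1 %.4f", x$best$dev_f1))
    cat("\n")
  } else {
    cat("  (untrained)\n")
  }
  invisible(x)
}

#' @export
summary.medtagger <- function(object, test = NULL, ...) {
  out <- list(model = object, history = object$history,
              test_eval = if (!is.null(test)) evaluate_tagger(object, test))
  class(out) <- "summary.medtagger"
  out
}

#' @export
print.summary.medtagger <- function(x, ...) {
  print(x$model)
  if (nrow(x$history)) {
    cat("\nTraining history:\n")
    print(x$history, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$test_eval)) {
    cat("\nHeld-out evaluation:\n")
    print(x$test_eval)
  }
  invisible(x)
}

#' @export
coef.medtagger <- function(object, ...) object$params

#' @export
plot.medtagger <- function(x, ...) {
  if (!nrow(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean CRF NLL",
                 main = "Training loss", ...)
  if (any(!is.na(h$dev_f1))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$dev_f1, type = "b", pch = 1, lty = 2,
                   axes = FALSE, xlab = "", ylab = "", col = "grey40",
                   ylim = c(0, 1))
    graphics::axis(4, col.axis = "grey40")
    graphics::mtext("dev entity F1", side = 4, line = -1.2, col = "grey40",
                    cex = 0.8)
  }
  invisible(x)
}

# ---- ablation and cross-validation ----------------------------------------

ablation_variants <- function(base) {
  list(
    full = base,
    no_dsn_csa = utils::modifyList(base, list(use_dsn_csa = FALSE)),
    no_mha = utils::modifyList(base, list(use_mha = FALSE)),
    no_ggnn = utils::modifyList(base, list(use_ggnn = FALSE)))
}

#' Ablation study
#'
#' Trains the full model and the three single-removal variants (no dual
#' stream / cross-stream attention, no multi-head attention, no graph
#' network) for each seed, and reports entity-level P/R/F1 on the test
#' split per variant with mean and standard deviation.
#'
#' @param train,test corpora of [labeled_sequence()] objects.
#' @param lex a [lexicon()].
#' @param config base [tagger_config()] (flags are toggled per variant).
#' @param trainer a [trainer_config()]; its seed is replaced per run.
#' @param seeds integer vector of training seeds.
#' @param dev optional dev corpus for early stopping.
#' @param verbose print progress.
#' @return list of class `ablation_result`: `runs` (per seed x variant
#'   data.frame with P, R, F1, n_params) and `summary` (per-variant mean/sd).
#' @export
run_ablation <- function(train, test, lex, config = tagger_config(),
                         trainer = trainer_config(), seeds = 1L,
                         dev = NULL, verbose = FALSE) {
  if (!length(seeds)) stop("need at least one seed")
  variants <- ablation_variants(unclass(config))
  runs <- list()
  for (seed in seeds) {
    for (vn in names(variants)) {
      cfg <- do.call(tagger_config, variants[[vn]])
      tr <- trainer
      tr$seed <- as.integer(seed)
      if (verbose) cat("ablation:", vn, "seed", seed, "\n")
      fit <- medtagger(train, lex, dev = dev, config = cfg, trainer = tr)
      ev <- evaluate_tagger(fit, test)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = vn, seed = seed, P = ev$overall$P, R = ev$overall$R,
        F1 = ev$overall$F1, n_params = n_params(fit),
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$variant), function(g) {
    data.frame(variant = g$variant[1], mean_F1 = mean(g$F1),
               sd_F1 = stats::sd(g$F1), mean_P = mean(g$P),
               mean_R = mean(g$R), n_params = g$n_params[1],
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg), class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Ablation summary (entity-level micro scores):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' k-fold cross-validation of the tagger
#'
#' @param corpus list of [labeled_sequence()] objects.
#' @param lex a [lexicon()].
#' @param k number of folds.
#' @param config,trainer model and training configuration.
#' @param seed shuffle seed for the folds.
#' @return data.frame with one row per fold (P, R, F1) plus mean/sd rows in
#'   the `"summary"` attribute.
#' @export
crossval_tagger <- function(corpus, lex, k = 5L, config = tagger_config(),
                            trainer = trainer_config(), seed = 1L) {
  folds <- kfold_split(corpus, k, seed = seed)
  rows <- lapply(seq_along(folds), function(f) {
    fit <- medtagger(folds[[f]]$train, lex, config = config,
                     trainer = trainer)
    ev <- evaluate_tagger(fit, folds[[f]]$validation)
    data.frame(fold = f, P = ev$overall$P, R = ev$overall$R,
               F1 = ev$overall$F1)
  })
  res <- do.call(rbind, rows)
  attr(res, "summary") <- data.frame(mean_F1 = mean(res$F1),
                                     sd_F1 = stats::sd(res$F1))
  res
}
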