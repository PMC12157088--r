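test_that("path score adds emissions and transitions as defined", {
  # n = 1: no transition term
  P1 <- matrix(c(0.3, -0.2), 1, 2)
  Tm <- matrix(0, 2, 2)
  expect_equal(crf_score(P1, Tm, 2L), -0.2)

  # hand-evaluated two-step example
  P <- matrix(c(0.5, 1.0, 0.2, 0.3), 2, 2, byrow = TRUE)
  Tm <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  expect_equal(crf_score(P, Tm, c(1L, 2L)), 0.5 + 0.2 + 0.3)

  # additivity: concatenation = S1 + S2 + bridging transition
  set.seed(1)
  L <- 3
  Tm <- matrix(rnorm(L * L), L, L)
  Pa <- matrix(rnorm(4 * L), 4, L); ya <- sample(1:L, 4, replace = TRUE)
  Pb <- matrix(rnorm(3 * L), 3, L); yb <- sample(1:L, 3, replace = TRUE)
  expect_equal(crf_score(rbind(Pa, Pb), Tm, c(ya, yb)),
               crf_score(Pa, Tm, ya) + crf_score(Pb, Tm, yb) +
                 Tm[ya[4], yb[1]])

  expect_error(crf_score(P, Tm, c(1L, 3L)), "unknown label")
  expect_error(crf_score(P, Tm, 1L), "length")
})

test_that("log-partition agrees with closed forms on degenerate instances", {
  # n = 1, two labels with zero scores: log 2
  expect_equal(crf_log_partition(matrix(0, 1, 2), matrix(0, 2, 2)), log(2))

  # single label: only one path
  P <- matrix(c(0.4, -1.2, 0.7), 3, 1)
  Tm <- matrix(0.3, 1, 1)
  expect_equal(crf_log_partition(P, Tm), sum(P) + 2 * 0.3)
  expect_equal(crf_nll(P, Tm, c(1L, 1L, 1L)), 0)
})

test_that("forward algorithm, NLL, and Viterbi agree with exhaustive enumeration", {
  set.seed(2024)
  for (rep in 1:200) {
    inst <- random_crf_instance(n_max = 5L, L_max = 4L)
    oracle <- enum_crf(inst$P, inst$T_mat)

    expect_equal(crf_log_partition(inst$P, inst$T_mat), oracle$logZ,
                 tolerance = 1e-6)

    gold_score <- crf_score(inst$P, inst$T_mat, inst$gold)
    p_gold <- exp(gold_score - oracle$logZ)
    expect_equal(crf_nll(inst$P, inst$T_mat, inst$gold), -log(p_gold),
                 tolerance = 1e-6)
    expect_gte(crf_nll(inst$P, inst$T_mat, inst$gold), -1e-6)

    vit <- viterbi_decode(inst$P, inst$T_mat)
    expect_identical(vit$path, oracle$best_path)
    expect_equal(vit$score, oracle$best_score, tolerance = 1e-9)
    expect_gte(vit$score + 1e-9, gold_score)
  }
})

test_that("path probabilities normalise and emissions shift both S and logZ", {
  set.seed(31)
  for (rep in 1:20) {
    inst <- random_crf_instance(n_max = 5L, L_max = 4L)
    oracle <- enum_crf(inst$P, inst$T_mat)
    expect_equal(sum(exp(oracle$scores - crf_log_partition(inst$P, inst$T_mat))),
                 1, tolerance = 1e-6)

    # adding c to every emission at one position shifts S and logZ by c
    i <- sample(nrow(inst$P), 1)
    cshift <- rnorm(1)
    P2 <- inst$P
    P2[i, ] <- P2[i, ] + cshift
    expect_equal(crf_log_partition(P2, inst$T_mat),
                 crf_log_partition(inst$P, inst$T_mat) + cshift,
                 tolerance = 1e-9)
    expect_equal(crf_score(P2, inst$T_mat, inst$gold),
                 crf_score(inst$P, inst$T_mat, inst$gold) + cshift,
                 tolerance = 1e-12)
    # so the NLL is shift-invariant
    expect_equal(crf_nll(P2, inst$T_mat, inst$gold),
                 crf_nll(inst$P, inst$T_mat, inst$gold), tolerance = 1e-8)
  }
})

test_that("Viterbi degenerates to argmax decoding when transitions are inert", {
  set.seed(6)
  P <- matrix(rnorm(12), 4, 3)
  vit <- viterbi_decode(P, matrix(0, 3, 3))
  expect_equal(vit$path, apply(P, 1, which.max))

  # n = 1: argmax over the single emission row
  v1 <- viterbi_decode(matrix(c(0.1, 0.9, 0.2), 1, 3), matrix(0, 3, 3))
  expect_equal(v1$path, 2L)

  # deterministic tie-break: all-zero scores decode to label 1 everywhere
  v0 <- viterbi_decode(matrix(0, 3, 2), matrix(0, 2, 2))
  expect_equal(v0$path, c(1L, 1L, 1L))
})

test_that("emission projection is the documented affine map", {
  p <- crf_params(c("O", "B-x"), d = 2, seed = 1)
  p$W_emit <- matrix(c(1, 2, 3, 4), 2, 2)
  p$b_emit <- c(0.5, -0.5)
  H <- matrix(c(1, 1), 1, 2)
  expect_equal(emission_scores(H, p), matrix(c(3.5, 6.5), 1, 2))

  # zero weights and bias give an all-zero table of contract shape
  p$W_emit <- matrix(0, 2, 2); p$b_emit <- c(0, 0)
  P <- emission_scores(matrix(rnorm(10), 5, 2), p)
  expect_equal(P, matrix(0, 5, 2))
})

test_that("optional boundary scores enter S and logZ consistently", {
  set.seed(13)
  inst <- random_crf_instance(n_max = 4L, L_max = 3L)
  L <- ncol(inst$P)
  start <- rnorm(L); stop <- rnorm(L)
  # enumeration with boundary terms
  oracle <- enum_crf(inst$P, inst$T_mat)
  n <- nrow(inst$P)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  sc <- oracle$scores + start[paths[, 1]] + stop[paths[, n]]
  expect_equal(crf_log_partition(inst$P, inst$T_mat, start = start,
                                 stop = stop),
               max(sc) + log(sum(exp(sc - max(sc)))), tolerance = 1e-6)
  vit <- viterbi_decode(inst$P, inst$T_mat, start = start, stop = stop)
  expect_equal(vit$score, max(sc), tolerance = 1e-9)
})

test_that("scheme mask forbids invalid BIO transitions during decoding", {
  labels <- c("O", "B-a", "I-a", "B-b", "I-b")
  mask <- bio_transition_mask(labels)
  expect_equal(mask["O", "I-a"], -Inf)
  expect_equal(mask["B-b", "I-a"], -Inf)
  expect_equal(mask["B-a", "I-a"], 0)
  expect_equal(mask["I-a", "I-a"], 0)

  # adversarial emissions that favour starting with I-: mask repairs it
  set.seed(99)
  for (rep in 1:10) {
    P <- matrix(rnorm(6 * 5, sd = 3), 6, 5)
    Tm <- matrix(rnorm(25), 5, 5)
    path <- viterbi_decode(P, Tm, mask = mask)$path
    expect_silent(validate_bio(labels[path]))
  }
})

test_that("a gradient step on the CRF NLL reduces it", {
  set.seed(55)
  P <- matrix(rnorm(8), 4, 2)
  params <- list(P = P, "crf.T" = matrix(rnorm(4), 2, 2))
  gold <- c(1L, 2L, 2L, 1L)
  nll_at <- function(pl) {
    tp <- medtagger:::ad_tape(pl)
    node <- medtagger:::ad_crf_nll(tp, medtagger:::ad_param(tp, "P"),
                                   "crf.T", gold)
    medtagger:::ad_val(tp, node)[1, 1]
  }
  tp <- medtagger:::ad_tape(params)
  node <- medtagger:::ad_crf_nll(tp, medtagger:::ad_param(tp, "P"),
                                 "crf.T", gold)
  before <- medtagger:::ad_val(tp, node)[1, 1]
  medtagger:::ad_backward(tp, node)
  g <- as.list(tp$pgrads)
  lr <- 0.05
  params2 <- list(P = params$P - lr * g$P,
                  "crf.T" = params$"crf.T" - lr * g$"crf.T")
  expect_lt(nll_at(params2), before)
})
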