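# Dual-stream network: independent per-stream feature transforms followed by
# cross-stream attention, where the character stream queries the word stream
# and vice versa, and the two attended streams are stacked row-wise.

#' Create dual-stream parameters
#'
#' The character stream consumes the fused n x 2d representation (affine
#' 2d -> d with tanh); the word stream consumes the m x d word embeddings
#' (affine d -> d with tanh). Query/key/value projections are shared across
#' the two streams by default (one set of projection matrices serves both
#' directions); `share_projections = FALSE` gives each stream its own.
#'
#' @param d hidden dimension.
#' @param seed RNG seed.
#' @param share_projections share Wq/Wk/Wv across streams (default TRUE).
#' @return object of class `stream_params`.
#' @export
stream_params <- function(d, seed = 1L, share_projections = TRUE) {
  set.seed(seed)
  p <- list(d = d,
            Wc = init_mat(2L * d, d), bc = rep(0, d),
            Ww = init_mat(d, d), bw = rep(0, d),
            Wq = init_mat(d, d), Wk = init_mat(d, d), Wv = init_mat(d, d),
            share_projections = share_projections)
  if (!share_projections) {
    p$Wq_w <- init_mat(d, d); p$Wk_w <- init_mat(d, d); p$Wv_w <- init_mat(d, d)
  }
  structure(p, class = "stream_params")
}

#' Transform the two streams independently
#'
#' Applies the per-stream feature-conversion functions: the fused
#' character-word matrix maps to an n x d stream, the word embeddings to an
#' m x d stream.
#'
#' @param H n x 2d fused character representation (see [fuse_char_word()]).
#' @param Hw m x d word-stream matrix (may have zero rows).
#' @param p a [stream_params()] object.
#' @return list with `Hc_prime` (n x d) and `Hw_prime` (m x d).
#' @export
transform_streams <- function(H, Hw, p) {
  if (ncol(H) != nrow(p$Wc)) {
    stop("fused input has ", ncol(H), " columns, expected ", nrow(p$Wc))
  }
  Hc_prime <- tanh(sweep(H %*% p$Wc, 2L, p$bc, "+"))
  Hw_prime <- if (is.null(Hw) || nrow(Hw) == 0) {
    matrix(0, 0L, p$d)
  } else {
    tanh(sweep(Hw %*% p$Ww, 2L, p$bw, "+"))
  }
  list(Hc_prime = Hc_prime, Hw_prime = Hw_prime)
}

#' Cross-stream attention
#'
#' The character stream attends over the word stream and the word stream
#' over the character stream, with scaled dot-product attention:
#' `Ac = softmax(Qc Kw' / sqrt(d)) Vw` and `Aw = softmax(Qw Kc' / sqrt(d)) Vc`.
#' The fused output stacks the two: `H_prime = rbind(Ac, Aw)`, (n+m) x d.
#'
#' With `word_attn_char_queries = TRUE` the word-side weights are instead
#' computed from the character queries against the character keys, a variant
#' formulation whose word-side output then has one row per character; the
#' default uses the word queries, i.e. attention from the word stream to the
#' character stream.
#'
#' When the word stream is empty (no lexicon match in the sentence) the
#' character stream passes through unchanged and the output is flagged with
#' `word_fallback = TRUE`.
#'
#' @param Hc_prime n x d transformed character stream.
#' @param Hw_prime m x d transformed word stream.
#' @param p a [stream_params()] object.
#' @param word_attn_char_queries use character queries (against character
#'   keys) for the word-side attention instead of word queries.
#' @param residual add each stream's input back onto its attended output
#'   (`Ac = Hc_prime + attn`, `Aw = Hw_prime + attn`). Off by default, which
#'   gives the pure attention formulation; the full model enables it because
#'   the pure form collapses the character stream to at most m distinct rows
#'   (see the methods vignette). No word-side residual is applied under
#'   `word_attn_char_queries`, whose word output has n rows.
#' @return list of class `cross_stream_output` with `Qc`, `Kw`, `Vw`, `Qw`,
#'   `Kc`, `Vc`, attention weight matrices `Wc_attn` (n x m) and `Ww_attn`
#'   (m x n), attended streams `Ac` (n x d) and `Aw` (m x d), the stacked
#'   `H_prime` ((n+m) x d), and `word_fallback`.
#' @export
cross_stream_attention <- function(Hc_prime, Hw_prime, p,
                                   word_attn_char_queries = FALSE,
                                   residual = FALSE) {
  d <- ncol(Hc_prime)
  if (nrow(Hw_prime) > 0 && ncol(Hw_prime) != d) {
    stop("stream dimension mismatch")
  }
  Wq_w <- if (isTRUE(p$share_projections)) p$Wq else p$Wq_w
  Wk_w <- if (isTRUE(p$share_projections)) p$Wk else p$Wk_w
  Wv_w <- if (isTRUE(p$share_projections)) p$Wv else p$Wv_w
  Qc <- Hc_prime %*% p$Wq; Kc <- Hc_prime %*% p$Wk; Vc <- Hc_prime %*% p$Wv
  if (nrow(Hw_prime) == 0) {
    return(structure(list(
      Qc = Qc, Kc = Kc, Vc = Vc,
      Qw = matrix(0, 0L, d), Kw = matrix(0, 0L, d), Vw = matrix(0, 0L, d),
      Wc_attn = matrix(0, nrow(Hc_prime), 0L),
      Ww_attn = matrix(0, 0L, nrow(Hc_prime)),
      Ac = Hc_prime, Aw = matrix(0, 0L, d),
      H_prime = Hc_prime, word_fallback = TRUE),
      class = "cross_stream_output"))
  }
  Qw <- Hw_prime %*% Wq_w; Kw <- Hw_prime %*% Wk_w; Vw <- Hw_prime %*% Wv_w
  Wc_attn <- softmax_rows(tcrossprod(Qc, Kw) / sqrt(d))
  q_word <- if (word_attn_char_queries) Qc else Qw
  Ww_attn <- softmax_rows(tcrossprod(q_word, Kc) / sqrt(d))
  Ac <- Wc_attn %*% Vw
  Aw <- Ww_attn %*% Vc
  if (residual) {
    Ac <- Hc_prime + Ac
    if (!word_attn_char_queries) Aw <- Hw_prime + Aw
  }
  structure(list(Qc = Qc, Kc = Kc, Vc = Vc, Qw = Qw, Kw = Kw, Vw = Vw,
                 Wc_attn = Wc_attn, Ww_attn = Ww_attn,
                 Ac = Ac, Aw = Aw, H_prime = rbind(Ac, Aw),
                 word_fallback = FALSE),
            class = "cross_stream_output")
}
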