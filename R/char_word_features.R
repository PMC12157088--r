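# Character-stream and word-stream feature extraction.
#
# Characters pass through a small trainable transformer encoder (learned
# embeddings + sinusoidal positions + self-attention/feed-forward blocks
# with residual connections). Words come from exhaustive dictionary matching
# against a domain lexicon; matched words are embedded via a trainable table
# and, for fusion with the character stream, pooled per character with
# frequency weights.

# Sinusoidal positional encoding (n x d, d even).
positional_encoding <- function(n, d) {
  stopifnot(d %% 2 == 0)
  pos <- seq_len(n) - 1
  i <- seq_len(d / 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, n, d)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

# Uniform init scaled by fan-in, the convention used across the model.
init_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

#' Create character-encoder parameters
#'
#' A compact transformer encoder: learned character embeddings plus fixed
#' sinusoidal positional encodings, followed by `depth` blocks of single-head
#' self-attention and a tanh feed-forward layer, each with a residual
#' connection. Small enough to train from scratch on a corpus; a pre-trained
#' checkpoint can be dropped in by supplying the same parameter structure.
#'
#' @param vocab character vector of known tokens; an `"<unk>"` entry is
#'   appended if absent, and unseen characters map to it.
#' @param d hidden dimension (even, so heads can split it downstream).
#' @param depth number of attention + feed-forward blocks.
#' @param seed RNG seed for initialisation.
#' @return object of class `char_encoder_params`.
#' @export
char_encoder_params <- function(vocab, d = 64L, depth = 2L, seed = 1L) {
  stopifnot(d > 0, d %% 2 == 0, depth >= 0)
  if (!"<unk>" %in% vocab) vocab <- c(vocab, "<unk>")
  set.seed(seed)
  blocks <- lapply(seq_len(depth), function(l) {
    list(Wq = init_mat(d, d), Wk = init_mat(d, d), Wv = init_mat(d, d),
         W1 = init_mat(d, d), b1 = rep(0, d),
         W2 = init_mat(d, d), b2 = rep(0, d))
  })
  structure(list(vocab = vocab, d = d, depth = depth,
                 E = init_mat(length(vocab), d), blocks = blocks),
            class = "char_encoder_params")
}

# Map characters to vocabulary indices, unknowns to "<unk>".
char_indices <- function(chars, vocab) {
  idx <- match(chars, vocab)
  idx[is.na(idx)] <- match("<unk>", vocab)
  idx
}

#' Encode a character sequence
#'
#' Deterministic forward pass of the character encoder: returns the n x d
#' matrix of contextual hidden states (one row per character).
#'
#' @param x a [labeled_sequence()] or character vector of tokens.
#' @param params a [char_encoder_params()] object.
#' @return n x d numeric matrix.
#' @export
encode_characters <- function(x, params) {
  chars <- if (inherits(x, "labeled_sequence")) x$chars else as.character(x)
  n <- length(chars)
  if (n == 0) stop("empty sequence: encoder requires n >= 1")
  d <- params$d
  H <- params$E[char_indices(chars, params$vocab), , drop = FALSE] +
    positional_encoding(n, d)
  for (blk in params$blocks) {
    Q <- H %*% blk$Wq; K <- H %*% blk$Wk; V <- H %*% blk$Wv
    A <- softmax_rows(tcrossprod(Q, K) / sqrt(d))
    H <- H + A %*% V
    F1 <- tanh(sweep(H %*% blk$W1, 2L, blk$b1, "+"))
    H <- H + sweep(F1 %*% blk$W2, 2L, blk$b2, "+")
  }
  H
}

#' Match lexicon words in a character sequence
#'
#' Exhaustive dictionary matching: every substring of length 2 to
#' `max_word_len` that appears in the lexicon is reported, for every
#' occurrence (single characters are already covered by the character
#' stream). Matches are ordered by (start, end).
#'
#' @param x a [labeled_sequence()] or character vector of tokens.
#' @param lex a [lexicon()] object.
#' @param max_word_len longest substring considered (default 8).
#' @param embeddings optional word-embedding matrix with one row per lexicon
#'   entry (lexicon order); when supplied, `Hw` holds the matched rows.
#' @return object of class `word_features`: list with `matches` (data.frame
#'   `word`, `start`, `end` 0-based half-open, `lex_index`, `frequency`),
#'   `m` (match count) and `Hw` (m x d matrix, or NULL without embeddings).
#' @export
match_lexicon <- function(x, lex, max_word_len = 8L, embeddings = NULL) {
  chars <- if (inherits(x, "labeled_sequence")) x$chars else as.character(x)
  stopifnot(max_word_len >= 1)
  n <- length(chars)
  lut <- new.env(parent = emptyenv(), size = max(16L, nrow(lex)))
  for (i in seq_len(nrow(lex))) assign(lex$word[i], i, envir = lut)
  word <- character(); start <- integer(); lex_index <- integer()
  len_max <- min(max_word_len, n)
  if (len_max >= 2 && nrow(lex) > 0) {
    for (s in seq_len(n - 1L)) {
      w <- chars[s]
      for (e in (s + 1L):min(n, s + len_max - 1L)) {
        w <- paste0(w, chars[e])
        hit <- get0(w, envir = lut, ifnotfound = NULL)
        if (!is.null(hit)) {
          word[[length(word) + 1L]] <- w
          start[[length(start) + 1L]] <- s - 1L
          lex_index[[length(lex_index) + 1L]] <- hit
        }
      }
    }
  }
  matches <- data.frame(word = word, start = start,
                        end = start + nchar(word),
                        lex_index = lex_index,
                        frequency = if (length(lex_index)) {
                          lex$frequency[lex_index]
                        } else numeric(),
                        stringsAsFactors = FALSE)
  matches <- matches[order(matches$start, matches$end), , drop = FALSE]
  rownames(matches) <- NULL
  Hw <- NULL
  if (!is.null(embeddings)) {
    Hw <- embeddings[matches$lex_index, , drop = FALSE]
  }
  structure(list(matches = matches, m = nrow(matches), Hw = Hw),
            class = "word_features")
}

# Frequency-weighted pooling matrix M (n x m): row i spreads weight over the
# matches covering character i, proportional to match frequency; rows with
# no covering match stay zero.
word_pooling_matrix <- function(n, matches) {
  m <- nrow(matches)
  M <- matrix(0, n, max(m, 0L))
  if (m == 0) return(M)
  for (j in seq_len(m)) {
    rows <- (matches$start[j] + 1L):matches$end[j]
    M[rows, j] <- matches$frequency[j]
  }
  rs <- rowSums(M)
  nz <- rs > 0
  M[nz, ] <- M[nz, , drop = FALSE] / rs[nz]
  M
}

#' Pool word features per character
#'
#' Row i of the result is the frequency-weighted mean of the embeddings of
#' all matched words covering character i (zero when none does). This
#' resolves the dimensional gap between the m-row word stream and the n-row
#' character stream before concatenation.
#'
#' @param wf a `word_features` object with `Hw` populated.
#' @param n sequence length.
#' @param d embedding dimension (required when `m == 0`).
#' @return n x d matrix.
#' @export
pool_word_features_per_char <- function(wf, n, d = ncol(wf$Hw)) {
  if (wf$m == 0) return(matrix(0, n, d))
  word_pooling_matrix(n, wf$matches) %*% wf$Hw
}

#' Fuse character and pooled word features
#'
#' Per-character concatenation of the character hidden state with the pooled
#' word feature: row i is `[Hc[i], pooled[i]]`, giving an n x 2d matrix.
#'
#' @param Hc n x d character feature matrix.
#' @param pooled n x d pooled word feature matrix.
#' @return n x 2d fused matrix.
#' @export
fuse_char_word <- function(Hc, pooled) {
  if (nrow(Hc) != nrow(pooled)) {
    stop("row-count mismatch: ", nrow(Hc), " vs ", nrow(pooled))
  }
  cbind(Hc, pooled)
}
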