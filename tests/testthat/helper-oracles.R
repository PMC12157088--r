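# Independent brute-force oracles used to pin down the dynamic programs and
# the dictionary matcher. These deliberately share no code with the package
# implementations.

# Enumerate all |L|^n label paths; returns scores for each, the argmax path
# (lowest label indices at the latest positions on ties, matching the
# documented tie-break), and the log-partition via log(sum(exp())).
enum_crf <- function(P, T_mat) {
  n <- nrow(P)
  L <- ncol(P)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(P[cbind(seq_len(n), y)])
    if (n > 1) s <- s + sum(T_mat[cbind(y[-n], y[-1])])
    s
  })
  # Column i of expand.grid is path position i and the LAST factor varies
  # slowest, so rows are ordered with position n as the most significant key:
  # the first maximal row realises the documented Viterbi tie-break (lowest
  # label index at the latest position).
  best <- which.max(scores)
  mx <- max(scores)
  list(scores = scores,
       logZ = mx + log(sum(exp(scores - mx))),
       best_path = as.integer(paths[best, ]),
       best_score = scores[best])
}

# All-substring dictionary matcher oracle: nested loops over every (start,
# length) pair, string comparison against the lexicon words.
brute_matches <- function(chars, lex, max_word_len) {
  n <- length(chars)
  out <- data.frame(word = character(), start = integer(), end = integer(),
                    lex_index = integer(), frequency = numeric(),
                    stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    for (e in s:min(n, s + max_word_len - 1L)) {
      if (e - s + 1L < 2L) next
      w <- paste(chars[s:e], collapse = "")
      i <- which(lex$word == w)
      if (length(i) == 1L) {
        out <- rbind(out, data.frame(word = w, start = s - 1L, end = e,
                                     lex_index = i,
                                     frequency = lex$frequency[i],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random non-overlapping span set over a sequence of length n.
random_span_set <- function(n, categories = c("a", "b")) {
  starts <- integer(); ends <- integer(); cats <- character()
  pos <- 0L
  while (pos < n) {
    gap <- sample(0:3, 1L)
    s <- pos + gap
    if (s >= n) break
    e <- min(n, s + sample(1:4, 1L))
    starts <- c(starts, s); ends <- c(ends, e)
    cats <- c(cats, sample(categories, 1L))
    pos <- e
  }
  entity_spans(starts, ends, cats)
}

# Small random CRF instance.
random_crf_instance <- function(n_max = 6L, L_max = 5L) {
  n <- sample(1:n_max, 1L)
  L <- sample(2:L_max, 1L)
  list(P = matrix(stats::rnorm(n * L, sd = 2), n, L),
       T_mat = matrix(stats::rnorm(L * L), L, L),
       gold = sample(seq_len(L), n, replace = TRUE))
}
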