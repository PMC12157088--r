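# Linear-chain conditional random field: path scoring, log-partition via the
# forward algorithm (log space), NLL, and exact Viterbi decoding.
#
# A path score is S(X, Y) = sum_i P_i(y_i) + sum_{i<n} T[y_i, y_{i+1}], with
# P the n x |L| emission table and T the |L| x |L| transition-score matrix.
# Optional start/stop score vectors extend S with start[y_1] + stop[y_n]
# (off by default).

#' Create CRF parameters
#'
#' @param labels ordered label inventory (character vector); the order is
#'   fixed and persisted — emissions and transitions index into it.
#' @param d feature dimension feeding the emission projection.
#' @param seed RNG seed for weight initialisation.
#' @param use_boundary include zero-initialised start/stop score vectors.
#' @return list of class `crf_params` with `labels`, `T_mat` (|L| x |L|),
#'   `W_emit` (d x |L|), `b_emit`, and optional `start`/`stop` vectors.
#' @export
crf_params <- function(labels, d, seed = 1L, use_boundary = FALSE) {
  stopifnot(length(labels) >= 1, d > 0)
  set.seed(seed)
  L <- length(labels)
  structure(list(
    labels = as.character(labels),
    T_mat = matrix(stats::runif(L * L, -0.1, 0.1), L, L,
                   dimnames = list(labels, labels)),
    W_emit = matrix(stats::runif(d * L, -1, 1) / sqrt(d), d, L),
    b_emit = rep(0, L),
    start = if (use_boundary) rep(0, L) else NULL,
    stop = if (use_boundary) rep(0, L) else NULL
  ), class = "crf_params")
}

#' Emission scores from final character representations
#'
#' Affine projection of the per-character rows of the final feature matrix
#' onto the label inventory. Only character rows carry labels, so callers
#' pass the first `n` rows of the fused character+word representation.
#'
#' @param H n x d matrix of per-character features.
#' @param params a [crf_params()] object.
#' @return n x |L| emission score matrix.
#' @export
emission_scores <- function(H, params) {
  P <- H %*% params$W_emit
  sweep(P, 2L, params$b_emit, "+")
}

check_path <- function(P, y) {
  if (length(y) != nrow(P)) {
    stop("label path length ", length(y), " != sequence length ", nrow(P))
  }
  if (any(y < 1L) || any(y > ncol(P))) stop("unknown label index in path")
}

# Gold-path score without boundary terms (shared with the autodiff node).
crf_path_score <- function(P, T_mat, y) {
  n <- nrow(P)
  s <- sum(P[cbind(seq_len(n), y)])
  if (n > 1L) s <- s + sum(T_mat[cbind(y[-n], y[-1L])])
  s
}

#' Score a label path
#'
#' @param P n x |L| emission table.
#' @param T_mat |L| x |L| transition score matrix (`T_mat[i, j]` scores the
#'   transition label i -> label j).
#' @param y integer label path (1-based indices into the label inventory).
#' @param start,stop optional boundary score vectors (length |L|).
#' @return scalar path score.
#' @export
crf_score <- function(P, T_mat, y, start = NULL, stop = NULL) {
  y <- as.integer(y)
  check_path(P, y)
  s <- crf_path_score(P, T_mat, y)
  if (!is.null(start)) s <- s + start[y[1L]]
  if (!is.null(stop)) s <- s + stop[y[length(y)]]
  s
}

# Forward table alpha[i, j] = log sum over paths ending at position i in
# label j of exp(partial score).
crf_forward_table <- function(P, T_mat, start = NULL) {
  n <- nrow(P); L <- ncol(P)
  alpha <- matrix(0, n, L)
  alpha[1L, ] <- P[1L, ] + if (is.null(start)) 0 else start
  if (n > 1L) {
    for (i in 2:n) {
      M <- T_mat + alpha[i - 1L, ]          # M[k, j] = alpha[k] + T[k, j]
      mx <- M[cbind(max.col(t(M), ties.method = "first"), seq_len(L))]
      alpha[i, ] <- mx + log(colSums(exp(M - matrix(mx, L, L, byrow = TRUE)))) +
        P[i, ]
    }
  }
  alpha
}

# Backward table beta[i, k] = log sum over path suffixes starting after
# position i given label k at position i.
crf_backward_table <- function(P, T_mat, stop = NULL) {
  n <- nrow(P); L <- ncol(P)
  beta <- matrix(0, n, L)
  beta[n, ] <- if (is.null(stop)) 0 else stop
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      b <- P[i + 1L, ] + beta[i + 1L, ]
      M <- T_mat + matrix(b, L, L, byrow = TRUE)  # M[k, j] = T[k, j] + b[j]
      mx <- M[cbind(seq_len(L), max.col(M, ties.method = "first"))]
      beta[i, ] <- mx + log(rowSums(exp(M - mx)))
    }
  }
  beta
}

#' Log-partition function (forward algorithm)
#'
#' Computes `log sum_Y exp(S(X, Y))` over all |L|^n label paths in O(n |L|^2)
#' time and in log space, avoiding the overflow of the naive exponential sum.
#'
#' @inheritParams crf_score
#' @return scalar log-partition value.
#' @export
crf_log_partition <- function(P, T_mat, start = NULL, stop = NULL) {
  n <- nrow(P)
  alpha <- crf_forward_table(P, T_mat, start = start)
  last <- alpha[n, ] + if (is.null(stop)) 0 else stop
  logsumexp(last)
}

#' CRF negative log-likelihood of a gold path
#'
#' `nll = logZ - S(X, Y_gold)`; non-negative up to numerical round-off.
#'
#' @inheritParams crf_score
#' @param y_gold integer gold label path.
#' @return scalar NLL.
#' @export
crf_nll <- function(P, T_mat, y_gold, start = NULL, stop = NULL) {
  crf_log_partition(P, T_mat, start = start, stop = stop) -
    crf_score(P, T_mat, y_gold, start = start, stop = stop)
}

#' Viterbi decoding
#'
#' Returns the label path maximising the CRF path score, by dynamic
#' programming. Ties are broken toward the lowest label index at the latest
#' position, so decoding is deterministic.
#'
#' @inheritParams crf_score
#' @param mask optional |L| x |L| matrix of 0 / -Inf added to `T_mat` to
#'   forbid transitions (e.g. a BIO scheme constraint); see
#'   [bio_transition_mask()].
#' @return list with `path` (integer vector) and `score`.
#' @export
viterbi_decode <- function(P, T_mat, start = NULL, stop = NULL, mask = NULL) {
  n <- nrow(P); L <- ncol(P)
  Tm <- if (is.null(mask)) T_mat else T_mat + mask
  delta <- P[1L, ] + if (is.null(start)) 0 else start
  if (!is.null(mask) && !is.null(attr(mask, "start"))) {
    delta <- delta + attr(mask, "start")
  }
  back <- matrix(0L, n, L)
  if (n > 1L) {
    for (i in 2:n) {
      M <- Tm + delta                      # M[k, j] = delta[k] + T[k, j]
      bp <- max.col(t(M), ties.method = "first")  # first max = lowest index
      delta <- M[cbind(bp, seq_len(L))] + P[i, ]
      back[i, ] <- bp
    }
  }
  if (!is.null(stop)) delta <- delta + stop
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (i in n:2) path[i - 1L] <- back[i, path[i]]
  }
  list(path = path, score = crf_score(P, T_mat, path, start = start,
                                      stop = stop))
}

#' BIO transition constraint mask
#'
#' Builds a 0 / -Inf matrix forbidding transitions into an `I-<cat>` tag from
#' anything other than `B-<cat>` or `I-<cat>`. Adding it to the transition
#' matrix yields scheme-constrained decoding (off by default in the model:
#' transitions are normally learned).
#'
#' @param labels label inventory containing `"O"`, `"B-*"`, `"I-*"` tags.
#' @return |L| x |L| matrix of 0 and -Inf, with a `"start"` attribute (length
#'   |L| vector of 0 / -Inf) forbidding I- tags at the first position;
#'   [viterbi_decode()] applies it automatically.
#' @export
bio_transition_mask <- function(labels) {
  L <- length(labels)
  mask <- matrix(0, L, L, dimnames = list(labels, labels))
  start <- rep(0, L)
  for (j in seq_len(L)) {
    tj <- split_tag(labels[j])
    if (tj$prefix != "I") next
    start[j] <- -Inf
    for (i in seq_len(L)) {
      ti <- split_tag(labels[i])
      ok <- ti$prefix %in% c("B", "I") && identical(ti$category, tj$category)
      if (!ok) mask[i, j] <- -Inf
    }
  }
  attr(mask, "start") <- start
  mask
}
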