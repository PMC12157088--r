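# Multi-head self-attention over the stacked character+word sequence, and
# gated-graph propagation (GRU-style node updates) over a character-word
# entity graph.

#' Create multi-head attention parameters
#'
#' Each of the `h` heads projects the d-dimensional input to d/h dimensions
#' with its own query/key/value matrices; head outputs are concatenated and
#' projected back to d by `Wo`.
#'
#' @param d model dimension (must be divisible by `h`).
#' @param h number of heads.
#' @param seed RNG seed.
#' @return object of class `mha_params`.
#' @export
mha_params <- function(d, h, seed = 1L) {
  if (h < 1) stop("h must be >= 1")
  if (d %% h != 0) stop("d (", d, ") not divisible by number of heads (", h, ")")
  set.seed(seed)
  dh <- d %/% h
  heads <- lapply(seq_len(h), function(i) {
    list(Wq = init_mat(d, dh), Wk = init_mat(d, dh), Wv = init_mat(d, dh))
  })
  structure(list(d = d, h = h, d_head = dh, heads = heads,
                 Wo = init_mat(d, d)),
            class = "mha_params")
}

#' Multi-head scaled dot-product self-attention
#'
#' @param H (n+m) x d input matrix.
#' @param p an [mha_params()] object.
#' @param return_weights also return the per-head attention weight matrices.
#' @return (n+m) x d output matrix; with `return_weights = TRUE`, a list with
#'   `H` and `weights` (list of row-stochastic matrices, one per head).
#' @export
multi_head_attention <- function(H, p, return_weights = FALSE) {
  if (ncol(H) != p$d) stop("input dimension ", ncol(H), " != d = ", p$d)
  scale <- sqrt(p$d_head)
  outs <- vector("list", p$h)
  wts <- vector("list", p$h)
  for (i in seq_len(p$h)) {
    hd <- p$heads[[i]]
    Q <- H %*% hd$Wq; K <- H %*% hd$Wk; V <- H %*% hd$Wv
    A <- softmax_rows(tcrossprod(Q, K) / scale)
    outs[[i]] <- A %*% V
    wts[[i]] <- A
  }
  out <- do.call(cbind, outs) %*% p$Wo
  if (return_weights) list(H = out, weights = wts) else out
}

# Adjacency from a coverage list: node n+j links to the characters in
# cov[[j]]; characters form a chain; every node has a self-loop.
graph_from_coverage <- function(n, cov, word_word_edges = FALSE) {
  m <- length(cov)
  N <- n + m
  A <- diag(1, N)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      A[i, i + 1L] <- 1; A[i + 1L, i] <- 1
    }
  }
  for (j in seq_len(m)) {
    A[n + j, cov[[j]]] <- 1
    A[cov[[j]], n + j] <- 1
  }
  if (word_word_edges && m > 1) {
    for (j in seq_len(m - 1L)) {
      for (k in (j + 1L):m) {
        if (length(intersect(cov[[j]], cov[[k]]))) {
          A[n + j, n + k] <- 1; A[n + k, n + j] <- 1
        }
      }
    }
  }
  A
}

#' Build the character-word entity graph
#'
#' Nodes 1..n are characters, nodes n+1..n+m the matched words. Edges:
#' adjacent characters (the sentence chain), each word to every character it
#' covers, and self-loops on all nodes (so every degree is >= 1).
#'
#' @param n number of characters.
#' @param matches match data.frame as in [match_lexicon()] (`start`, `end`,
#'   0-based half-open), or NULL for no word nodes.
#' @param word_word_edges also connect words whose spans overlap.
#' @return object of class `entity_graph`: list with binary symmetric
#'   adjacency `A`, degree vector `deg`, and normalised adjacency `A_norm`.
#' @export
build_entity_graph <- function(n, matches = NULL, word_word_edges = FALSE) {
  cov <- if (is.null(matches) || nrow(matches) == 0) {
    list()
  } else {
    if (any(matches$start < 0) || any(matches$end > n)) {
      stop("match span outside [0, n)")
    }
    lapply(seq_len(nrow(matches)), function(j) {
      (matches$start[j] + 1L):matches$end[j]
    })
  }
  A <- graph_from_coverage(n, cov, word_word_edges)
  structure(list(A = A, deg = rowSums(A), A_norm = normalize_adjacency(A)),
            class = "entity_graph")
}

#' Symmetric normalisation of an adjacency matrix
#'
#' Computes `D^{-1/2} A D^{-1/2}` with D the degree matrix. Requires every
#' row degree >= 1 (guaranteed when A has self-loops).
#'
#' @param A square binary symmetric adjacency matrix.
#' @return normalised adjacency, symmetric.
#' @export
normalize_adjacency <- function(A) {
  deg <- rowSums(A)
  if (any(deg < 1)) stop("zero-degree node: adjacency must include self-loops")
  dinv <- 1 / sqrt(deg)
  A * outer(dinv, dinv)
}

#' Create gated-graph-network parameters
#'
#' One propagation round computes the neighbourhood message
#' `Ht_tilde = A_norm %*% H %*% Wg` and applies a GRU-style update with
#' update gate Z, reset gate R and candidate state:
#' \preformatted{
#'   Z  = sigmoid(Ht_tilde Wz + H Uz + bz)
#'   R  = sigmoid(Ht_tilde Wr + H Ur + br)
#'   Hc = tanh(Ht_tilde Wh + (R * H) Uh + bh)
#'   H' = (1 - Z) * H + Z * Hc
#' }
#' Gate biases start at zero, so at initialisation the update follows the
#' bias-free form exactly.
#'
#' @param d node feature dimension.
#' @param T_rounds number of propagation rounds (>= 0).
#' @param seed RNG seed.
#' @return object of class `ggnn_params`.
#' @export
ggnn_params <- function(d, T_rounds = 2L, seed = 1L) {
  stopifnot(T_rounds >= 0)
  set.seed(seed)
  structure(list(d = d, T_rounds = as.integer(T_rounds),
                 Wg = init_mat(d, d),
                 Wz = init_mat(d, d), Uz = init_mat(d, d),
                 Wr = init_mat(d, d), Ur = init_mat(d, d),
                 Wh = init_mat(d, d), Uh = init_mat(d, d),
                 bz = matrix(0, 1L, d), br = matrix(0, 1L, d),
                 bh = matrix(0, 1L, d)),
            class = "ggnn_params")
}

# One GRU-gated propagation round over plain matrices.
ggnn_step <- function(H, A_norm, p, z_override = NULL) {
  Ht <- A_norm %*% H %*% p$Wg
  Z <- if (is.null(z_override)) {
    1 / (1 + exp(-sweep(Ht %*% p$Wz + H %*% p$Uz, 2L, p$bz, "+")))
  } else {
    matrix(z_override, nrow(H), ncol(H))
  }
  R <- 1 / (1 + exp(-sweep(Ht %*% p$Wr + H %*% p$Ur, 2L, p$br, "+")))
  Hc <- tanh(sweep(Ht %*% p$Wh + (R * H) %*% p$Uh, 2L, p$bh, "+"))
  (1 - Z) * H + Z * Hc
}

#' Gated graph propagation
#'
#' Runs `T_rounds` rounds of normalised-adjacency message passing with
#' GRU-gated node updates (see [ggnn_params()]). `T_rounds = 0` returns the
#' input unchanged.
#'
#' @param H0 (n+m) x d initial node features.
#' @param graph an [entity_graph()] (or any list with `A_norm`).
#' @param p a [ggnn_params()] object.
#' @param z_override force the update gate to a constant (testing hook: 0
#'   freezes the state, 1 replaces it with the candidate).
#' @return (n+m) x d matrix after propagation.
#' @export
ggnn_propagate <- function(H0, graph, p, z_override = NULL) {
  if (nrow(H0) != nrow(graph$A_norm)) {
    stop("node count mismatch: features ", nrow(H0), ", graph ",
         nrow(graph$A_norm))
  }
  H <- H0
  for (t in seq_len(p$T_rounds)) {
    H <- ggnn_step(H, graph$A_norm, p, z_override = z_override)
  }
  H
}
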