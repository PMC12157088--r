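# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Each tape node is a small environment holding the forward value (`v`), the
# accumulated gradient (`g`, NULL until the backward sweep reaches it) and a
# backward closure (`bw`) that pushes gradient into the node's parents or —
# for parameter leaves — into the tape's parameter-gradient environment.
# Keeping value and gradient inside per-node environments means the hot loops
# only ever mutate environments in place; the tape's ordered node list is
# written once per node and read only by the backward sweep, so R never
# copies a shared list spine.
#
# Every value is a base-R numeric matrix; scalars are 1x1 matrices. All
# functions here are internal: the exported model API sits on top.

ad_tape <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$cap <- 512L
  tp$n <- 0L
  tp$params <- params
  tp$pgrads <- new.env(parent = emptyenv())
  tp
}

ad_node <- function(tp, val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- val
  nd$g <- NULL
  nd$bw <- bw
  n <- tp$n + 1L
  if (n > tp$cap) {
    length(tp$nodes) <- 2L * n
    tp$cap <- 2L * n
  }
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

# Forward value of a node (tape argument kept for call-site clarity).
ad_val <- function(tp, node) node$v

ad_acc <- function(node, g) {
  cur <- node$g
  node$g <- if (is.null(cur)) g else cur + g
}

ad_pacc <- function(tp, name, g) {
  cur <- get0(name, envir = tp$pgrads, ifnotfound = NULL)
  assign(name, if (is.null(cur)) g else cur + g, envir = tp$pgrads)
}

# Run the backward sweep from `root` (normally the scalar loss node).
ad_backward <- function(tp, root) {
  root$g <- matrix(1, nrow(root$v), ncol(root$v))
  for (i in tp$n:1L) {
    nd <- tp$nodes[[i]]
    g <- nd$g
    if (!is.null(g) && !is.null(nd$bw)) nd$bw(g)
  }
  invisible(tp$pgrads)
}

# ---- leaves --------------------------------------------------------------

ad_const <- function(tp, x) ad_node(tp, x)

ad_param <- function(tp, name) {
  ad_node(tp, tp$params[[name]], function(g) ad_pacc(tp, name, g))
}

# Row lookup into a parameter matrix (embedding gather). `idx` may repeat.
ad_embed <- function(tp, name, idx) {
  E <- tp$params[[name]]
  nc <- ncol(E); nr <- nrow(E)
  ad_node(tp, E[idx, , drop = FALSE], function(g) {
    rs <- rowsum(g, group = idx)
    G <- matrix(0, nr, nc)
    G[as.integer(rownames(rs)), ] <- rs
    ad_pacc(tp, name, G)
  })
}

# ---- linear algebra ------------------------------------------------------

ad_matmul <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ad_node(tp, A %*% B, function(g) {
    ad_acc(a, tcrossprod(g, B))
    ad_acc(b, crossprod(A, g))
  })
}

# A %*% t(B) without materialising the transpose.
ad_matmul_nt <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ad_node(tp, tcrossprod(A, B), function(g) {
    ad_acc(a, g %*% B)
    ad_acc(b, crossprod(g, A))
  })
}

ad_add <- function(tp, a, b) {
  ad_node(tp, a$v + b$v, function(g) {
    ad_acc(a, g)
    ad_acc(b, g)
  })
}

# Add a 1 x k bias row to every row of an n x k matrix.
ad_add_bias <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ad_node(tp, A + matrix(B, nrow(A), ncol(A), byrow = TRUE), function(g) {
    ad_acc(a, g)
    ad_acc(b, matrix(colSums(g), 1L))
  })
}

ad_scale <- function(tp, a, s) {
  ad_node(tp, a$v * s, function(g) ad_acc(a, g * s))
}

ad_mul <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ad_node(tp, A * B, function(g) {
    ad_acc(a, g * B)
    ad_acc(b, g * A)
  })
}

ad_one_minus <- function(tp, a) {
  ad_node(tp, 1 - a$v, function(g) ad_acc(a, -g))
}

# ---- nonlinearities ------------------------------------------------------

ad_tanh <- function(tp, a) {
  Y <- tanh(a$v)
  ad_node(tp, Y, function(g) ad_acc(a, g * (1 - Y * Y)))
}

ad_sigmoid <- function(tp, a) {
  Y <- 1 / (1 + exp(-a$v))
  ad_node(tp, Y, function(g) ad_acc(a, g * Y * (1 - Y)))
}

# Row-wise softmax; Jacobian-vector product uses the standard identity
# dA = Y * (g - rowSums(g * Y)).
ad_softmax_rows <- function(tp, a) {
  Y <- softmax_rows(a$v)
  ad_node(tp, Y, function(g) {
    ad_acc(a, Y * (g - rowSums(g * Y)))
  })
}

# ---- shape ops -----------------------------------------------------------

ad_rbind <- function(tp, a, b) {
  A <- a$v; B <- b$v
  na <- nrow(A)
  ad_node(tp, rbind(A, B), function(g) {
    ad_acc(a, g[seq_len(na), , drop = FALSE])
    if (nrow(B) > 0) ad_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ka <- ncol(A)
  ad_node(tp, cbind(A, B), function(g) {
    ad_acc(a, g[, seq_len(ka), drop = FALSE])
    ad_acc(b, g[, -seq_len(ka), drop = FALSE])
  })
}

ad_rows <- function(tp, a, idx) {
  A <- a$v
  nr <- nrow(A); nc <- ncol(A)
  ad_node(tp, A[idx, , drop = FALSE], function(g) {
    rs <- rowsum(g, group = idx)
    G <- matrix(0, nr, nc)
    G[as.integer(rownames(rs)), ] <- rs
    ad_acc(a, G)
  })
}

# ---- CRF negative log-likelihood with analytic gradient ------------------
#
# Gradient of logZ w.r.t. emissions is the unary marginal table and w.r.t.
# transitions the expected transition counts (forward-backward); subtracting
# the observed gold one-hots gives the NLL gradient.
ad_crf_nll <- function(tp, p_node, trans_name, gold) {
  P <- p_node$v
  Tm <- tp$params[[trans_name]]
  n <- nrow(P); L <- ncol(P)
  alpha <- crf_forward_table(P, Tm)
  logZ <- logsumexp(alpha[n, ])
  s_gold <- crf_path_score(P, Tm, gold)
  nll <- logZ - s_gold
  ad_node(tp, matrix(nll, 1L, 1L), function(g) {
    gs <- g[1L, 1L]
    beta <- crf_backward_table(P, Tm)
    marg <- exp(alpha + beta - logZ)
    dP <- marg
    dP[cbind(seq_len(n), gold)] <- dP[cbind(seq_len(n), gold)] - 1
    ad_acc(p_node, gs * dP)
    if (n > 1L) {
      E <- matrix(0, L, L)
      for (i in seq_len(n - 1L)) {
        b <- P[i + 1L, ] + beta[i + 1L, ]
        M <- Tm + alpha[i, ] + matrix(b, L, L, byrow = TRUE)
        E <- E + exp(M - logZ)
        E[gold[i], gold[i + 1L]] <- E[gold[i], gold[i + 1L]] - 1
      }
      ad_pacc(tp, trans_name, gs * E)
    }
  })
}

# ---- shared numeric helpers ---------------------------------------------

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}
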