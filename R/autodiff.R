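# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Nodes are environments holding $value (matrix), $grad (accumulated
# cotangent), $parents (list of nodes) and $backfn (function mapping the
# node's grad to a list of parent grads). A tape (creation-order list)
# drives the reverse sweep. This is deliberately small: just the operations
# the segmentation network needs, each with a hand-derived backward rule.

ad_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

ad_node <- function(tape, value, parents = list(), backfn = NULL,
                    is_param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$is_param <- is_param
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

ad_const <- function(tape, x) ad_node(tape, as.matrix(x))

ad_param <- function(tape, x) ad_node(tape, as.matrix(x), is_param = TRUE)

.acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

# reverse sweep from a scalar loss node (grad seeded with 1)
ad_backward <- function(tape, loss_node) {
  loss_node$grad <- matrix(1, 1, 1)
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pgrads <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents))
      if (!is.null(pgrads[[j]])) .acc_grad(nd$parents[[j]], pgrads[[j]])
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# add a 1 x d bias row to every row of x
ad_add_bias <- function(tape, x, b) {
  ad_node(tape, sweep(x$value, 2L, as.numeric(b$value), "+"), list(x, b),
          function(g) list(g, matrix(colSums(g), 1)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_relu <- function(tape, x) {
  mask <- x$value > 0
  ad_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

ad_concat_cols <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ad_gather_rows <- function(tape, x, idx) {
  idx <- as.integer(idx)
  n <- nrow(x$value)
  ad_node(tape, x$value[idx, , drop = FALSE], list(x), function(g) {
    list(.scatter_add(matrix(0, n, ncol(g)), idx, g))
  })
}

# add the rows of `contrib` into `acc` at (possibly repeated) row indices
.scatter_add <- function(acc, idx, contrib) {
  s <- rowsum(contrib, group = idx)
  rows <- as.integer(rownames(s))
  acc[rows, ] <- acc[rows, , drop = FALSE] + s
  acc
}

# max-pool features over neighbourhoods: out[i, ] = colwise max over
# x[idx[i, ], ]. idx is an M x k integer matrix into the rows of x.
ad_group_max <- function(tape, x, idx) {
  m <- nrow(idx); k <- ncol(idx); d <- ncol(x$value)
  out <- x$value[idx[, 1], , drop = FALSE]
  arg <- matrix(idx[, 1], m, d)
  if (k > 1L) for (l in 2:k) {
    cand <- x$value[idx[, l], , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    arg[better] <- matrix(idx[, l], m, d)[better]
  }
  n <- nrow(x$value)
  ad_node(tape, out, list(x), function(g) {
    gx <- matrix(0, n, d)
    # route each gradient entry to the row that won the max
    for (j in seq_len(d)) {
      s <- rowsum(g[, j], group = arg[, j])
      rows <- as.integer(rownames(s))
      gx[rows, j] <- gx[rows, j] + as.numeric(s)
    }
    list(gx)
  })
}

# inverse-distance interpolation: out[i, ] = sum_l w[i, l] * x[idx[i, l], ]
# with constant weights w (rows sum to 1) and constant indices idx.
ad_interp <- function(tape, x, idx, w) {
  m <- nrow(idx); k <- ncol(idx); d <- ncol(x$value); n <- nrow(x$value)
  out <- matrix(0, m, d)
  for (l in seq_len(k))
    out <- out + w[, l] * x$value[idx[, l], , drop = FALSE]
  ad_node(tape, out, list(x), function(g) {
    gx <- matrix(0, n, d)
    for (l in seq_len(k))
      gx <- .scatter_add(gx, idx[, l], w[, l] * g)
    list(gx)
  })
}

# scaled dot-product attention restricted to kNN patches. q, k, v are node
# matrices aligned to the same point set; idx (M x kn) lists each point's
# patch members (rows of k/v). Scores are scaled by 1/scale.
ad_local_attention <- function(tape, q, k, v, idx, scale) {
  m <- nrow(idx); kn <- ncol(idx); d <- ncol(v$value)
  S <- matrix(0, m, kn)
  for (l in seq_len(kn))
    S[, l] <- rowSums(q$value * k$value[idx[, l], , drop = FALSE]) / scale
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  A <- E / rowSums(E)
  out <- matrix(0, m, d)
  for (l in seq_len(kn))
    out <- out + A[, l] * v$value[idx[, l], , drop = FALSE]
  nq <- nrow(q$value)
  attn <- A
  ad_node(tape, out, list(q, k, v), function(g) {
    dA <- matrix(0, m, kn)
    gv <- matrix(0, nq, d)
    for (l in seq_len(kn)) {
      dA[, l] <- rowSums(g * v$value[idx[, l], , drop = FALSE])
      gv <- .scatter_add(gv, idx[, l], attn[, l] * g)
    }
    dS <- attn * (dA - rowSums(dA * attn))  # rowwise softmax backward
    dS <- dS / scale
    gq <- matrix(0, m, ncol(q$value))
    gk <- matrix(0, nq, ncol(k$value))
    for (l in seq_len(kn)) {
      gq <- gq + dS[, l] * k$value[idx[, l], , drop = FALSE]
      gk <- .scatter_add(gk, idx[, l], dS[, l] * q$value)
    }
    list(gq, gk, gv)
  }) -> nd
  nd$attention <- A  # row-stochastic weights, exposed for inspection/tests
  nd
}

# feature normalization over the points of one cloud (per-column), with
# learnable gain/offset. Statistics are per-cloud at train and eval time, so
# single-cloud inference is deterministic and batch-size independent.
ad_batchnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  n <- nrow(x$value)
  mu <- colMeans(x$value)
  xc <- sweep(x$value, 2L, mu)
  va <- colMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  g_row <- as.numeric(gamma$value)
  b_row <- as.numeric(beta$value)
  out <- sweep(sweep(xhat, 2L, g_row, "*"), 2L, b_row, "+")
  ad_node(tape, out, list(x, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1)
    dbeta <- matrix(colSums(g), 1)
    dxhat <- sweep(g, 2L, g_row, "*")
    # standard batchnorm backward over the n points
    t1 <- dxhat
    t2 <- matrix(colMeans(dxhat), n, ncol(g), byrow = TRUE)
    t3 <- xhat * matrix(colMeans(dxhat * xhat), n, ncol(g), byrow = TRUE)
    dx <- sweep(t1 - t2 - t3, 2L, istd, "*")
    list(dx, dgamma, dbeta)
  })
}

# softmax cross-entropy head: returns the scalar mean loss node; labels are
# 0-based integers. The backward rule differentiates straight to the logits.
ad_softmax_xent <- function(tape, logits, labels0) {
  z <- logits$value
  n <- nrow(z)
  zs <- z - apply(z, 1L, max)
  ez <- exp(zs)
  p <- ez / rowSums(ez)
  li <- cbind(seq_len(n), labels0 + 1L)
  loss <- -mean(log(pmax(p[li], 1e-300)))
  ad_node(tape, matrix(loss, 1, 1), list(logits), function(g) {
    dz <- p
    dz[li] <- dz[li] - 1
    list(as.numeric(g) * dz / n)
  })
}
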