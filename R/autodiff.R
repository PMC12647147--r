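# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix.  Ops push a node holding the
# value, the parent ids, and a closure mapping the incoming gradient to the
# parent gradients.  One tape is built per molecule forward pass; gradients
# are accumulated per named parameter across a minibatch and applied with
# Adam.  Intentionally small: only the ops the encoder needs.

.tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$vals <- list(); t$par <- list(); t$bw <- list()
  t$n <- 0L; t$param_ids <- list()
  t
}

.tp <- function(tape, value, parents = integer(0), backward = NULL) {
  # force the promises first: a nested op call inside `value`/`parents`
  # must claim its tape id before this node does, keeping creation order
  # topological for the reverse sweep
  force(value); force(parents); force(backward)
  n <- tape$n + 1L
  tape$n <- n
  tape$vals[[n]] <- value
  tape$par[[n]] <- parents
  tape$bw[[n]] <- backward
  n
}

.val <- function(tape, id) {
  force(id)            # id may be an op call that grows the tape; run it first
  tape$vals[[id]]
}

ad_const <- function(tape, v) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  .tp(tape, v)
}

# leaf node for a named parameter; cached so each parameter appears once
ad_param <- function(tape, params, name) {
  id <- tape$param_ids[[name]]
  if (!is.null(id)) return(id)
  id <- .tp(tape, params[[name]])
  tape$param_ids[[name]] <- id
  id
}

ad_mm <- function(tape, a, b) {
  A <- .val(tape, a); B <- .val(tape, b)
  .tp(tape, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), t(A) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  .tp(tape, .val(tape, a) + .val(tape, b), c(a, b),
      function(g) list(g, g))
}

# matrix plus broadcast row vector (1 x k bias)
ad_add_vec <- function(tape, a, b) {
  A <- .val(tape, a); B <- .val(tape, b)
  .tp(tape, sweep(A, 2, as.numeric(B), "+"), c(a, b), function(g) {
    list(g, matrix(colSums(g), 1))
  })
}

ad_sub <- function(tape, a, b) {
  .tp(tape, .val(tape, a) - .val(tape, b), c(a, b),
      function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  A <- .val(tape, a); B <- .val(tape, b)
  .tp(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_smul <- function(tape, a, s) {
  .tp(tape, .val(tape, a) * s, a, function(g) list(g * s))
}

ad_relu <- function(tape, a) {
  A <- .val(tape, a)
  .tp(tape, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

ad_sigmoid <- function(tape, a) {
  S <- 1 / (1 + exp(-.val(tape, a)))
  .tp(tape, S, a, function(g) list(g * S * (1 - S)))
}

ad_softmax_rows <- function(tape, a) {
  A <- .val(tape, a)
  E <- exp(A - apply(A, 1, max))
  S <- E / rowSums(E)
  .tp(tape, S, a, function(g) {
    list((g - rowSums(g * S)) * S)
  })
}

ad_sum <- function(tape, a) {
  A <- .val(tape, a)
  .tp(tape, matrix(sum(A), 1, 1), a, function(g) {
    list(matrix(g[1, 1], nrow(A), ncol(A)))
  })
}

ad_colmeans <- function(tape, a) {
  A <- .val(tape, a)
  .tp(tape, matrix(colMeans(A), 1), a, function(g) {
    list(matrix(rep(as.numeric(g) / nrow(A), each = nrow(A)), nrow(A)))
  })
}

ad_rows <- function(tape, a, idx) {
  A <- .val(tape, a)
  .tp(tape, A[idx, , drop = FALSE], a, function(g) {
    Z <- matrix(0, nrow(A), ncol(A))
    for (k in seq_along(idx)) Z[idx[k], ] <- Z[idx[k], ] + g[k, ]
    list(Z)
  })
}

ad_cols <- function(tape, a, idx) {
  A <- .val(tape, a)
  .tp(tape, A[, idx, drop = FALSE], a, function(g) {
    Z <- matrix(0, nrow(A), ncol(A))
    Z[, idx] <- g
    list(Z)
  })
}

ad_rbind <- function(tape, ids) {
  vals <- lapply(ids, .val, tape = tape)
  rows <- vapply(vals, nrow, 0L)
  .tp(tape, do.call(rbind, vals), as.integer(ids), function(g) {
    stops <- cumsum(rows); starts <- c(1L, head(stops, -1L) + 1L)
    lapply(seq_along(ids), function(k) g[starts[k]:stops[k], , drop = FALSE])
  })
}

ad_cbind <- function(tape, ids) {
  vals <- lapply(ids, .val, tape = tape)
  cols <- vapply(vals, ncol, 0L)
  .tp(tape, do.call(cbind, vals), as.integer(ids), function(g) {
    stops <- cumsum(cols); starts <- c(1L, head(stops, -1L) + 1L)
    lapply(seq_along(ids), function(k) g[, starts[k]:stops[k], drop = FALSE])
  })
}

ad_transpose <- function(tape, a) {
  .tp(tape, t(.val(tape, a)), a, function(g) list(t(g)))
}

# row-wise layer normalization with learned gain/bias (1 x k each)
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  X <- .val(tape, a); G <- .val(tape, gamma); B <- .val(tape, beta)
  k <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  Y <- sweep(sweep(xhat, 2, as.numeric(G), "*"), 2, as.numeric(B), "+")
  .tp(tape, Y, c(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, as.numeric(G), "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(dx,
         matrix(colSums(g * xhat), 1),
         matrix(colSums(g), 1))
  })
}

# n x n matrix of squared euclidean distances between rows of X (n x 3)
ad_pairsqdist <- function(tape, x) {
  X <- .val(tape, x)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * X %*% t(X)
  D2[D2 < 0] <- 0
  .tp(tape, D2, x, function(g) {
    W <- g + t(g)
    list(2 * (rowSums(W) * X - W %*% X))
  })
}

# masked mean binary cross-entropy on logits (numerically stable)
ad_bce_logits <- function(tape, z, y, mask) {
  Z <- .val(tape, z)
  nobs <- max(sum(mask), 1)
  loss <- sum((pmax(Z, 0) - Z * y + log1p(exp(-abs(Z)))) * mask) / nobs
  .tp(tape, matrix(loss, 1, 1), z, function(g) {
    list(g[1, 1] * (1 / (1 + exp(-Z)) - y) * mask / nobs)
  })
}

# masked mean squared error
ad_mse <- function(tape, z, y, mask) {
  Z <- .val(tape, z)
  nobs <- max(sum(mask), 1)
  loss <- sum((Z - y)^2 * mask) / nobs
  .tp(tape, matrix(loss, 1, 1), z, function(g) {
    list(g[1, 1] * 2 * (Z - y) * mask / nobs)
  })
}

# inverted dropout; `mask` drawn by the caller so the RNG stream is owned
# by the training loop
ad_dropout <- function(tape, a, mask, rate) {
  .tp(tape, .val(tape, a) * mask / (1 - rate), a, function(g) {
    list(g * mask / (1 - rate))
  })
}

# reverse sweep; returns gradients for every named parameter on the tape
ad_backward <- function(tape, loss_id) {
  g <- vector("list", tape$n)
  g[[loss_id]] <- matrix(1, 1, 1)
  for (i in tape$n:1) {
    gi <- g[[i]]
    if (is.null(gi)) next
    bw <- tape$bw[[i]]
    if (is.null(bw)) next
    pg <- bw(gi)
    ps <- tape$par[[i]]
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      p <- ps[k]
      g[[p]] <- if (is.null(g[[p]])) pg[[k]] else g[[p]] + pg[[k]]
    }
  }
  out <- list()
  for (nm in names(tape$param_ids)) out[[nm]] <- g[[tape$param_ids[[nm]]]]
  out
}

# --- parameter store and optimizer ------------------------------------------

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

.adam_new <- function() {
  o <- new.env(parent = emptyenv())
  o$m <- list(); o$v <- list(); o$t <- 0L
  o
}

.adam_step <- function(opt, params, grads, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
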