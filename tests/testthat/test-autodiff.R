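# Reverse-mode tape: every op's backward is checked against central finite
# differences, plus a composite network and the optimizer.

num_grad_check <- function(fwd, X0, extra = NULL, tol = 1e-5) {
  # fwd(tape, x_id) -> output node id; extra constants must be created
  # outside fwd so repeated calls see identical values
  tape <- chemformer:::.tape_new()
  x <- chemformer:::ad_const(tape, X0)
  tape$param_ids[["x"]] <- x
  out <- fwd(tape, x)
  set.seed(99)
  R <- matrix(stats::rnorm(length(chemformer:::.val(tape, out))),
              nrow(chemformer:::.val(tape, out)))
  loss <- chemformer:::ad_sum(tape, chemformer:::ad_mul(
    tape, out, chemformer:::ad_const(tape, R)))
  g <- chemformer:::ad_backward(tape, loss)$x
  expect_false(is.null(g))
  lossv <- function(Xp) {
    t2 <- chemformer:::.tape_new()
    x2 <- chemformer:::ad_const(t2, Xp)
    sum(chemformer:::.val(t2, fwd(t2, x2)) * R)
  }
  worst <- 0
  for (i in seq_along(X0)) {
    Xp <- X0; eps <- 1e-6
    Xp[i] <- Xp[i] + eps; lp <- lossv(Xp)
    Xp[i] <- Xp[i] - 2 * eps; lm <- lossv(Xp)
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])))
  }
  expect_lt(worst, tol)
}

test_that("elementary op gradients match finite differences", {
  set.seed(12)
  A <- matrix(rnorm(12) + 0.3, 4, 3)   # offset avoids ReLU kinks
  W <- matrix(rnorm(15), 3, 5)
  bias <- matrix(rnorm(3), 1)
  G <- matrix(1 + rnorm(3, sd = 0.2), 1); B <- matrix(rnorm(3), 1)
  cc <- chemformer:::ad_const
  num_grad_check(function(t, x) chemformer:::ad_mm(t, x, cc(t, W)), A)
  num_grad_check(function(t, x) chemformer:::ad_relu(t, x), A)
  num_grad_check(function(t, x) chemformer:::ad_sigmoid(t, x), A)
  num_grad_check(function(t, x) chemformer:::ad_softmax_rows(t, x), A)
  num_grad_check(function(t, x) chemformer:::ad_add_vec(t, x, cc(t, bias)), A)
  num_grad_check(function(t, x) chemformer:::ad_rows(t, x, c(2, 1, 2, 4)), A)
  num_grad_check(function(t, x) chemformer:::ad_cols(t, x, c(3, 1)), A)
  num_grad_check(function(t, x) chemformer:::ad_rbind(t, list(x, x)), A)
  num_grad_check(function(t, x) chemformer:::ad_cbind(t, list(x, x)), A)
  num_grad_check(function(t, x) chemformer:::ad_transpose(t, x), A)
  num_grad_check(function(t, x) chemformer:::ad_colmeans(t, x), A)
  num_grad_check(function(t, x) chemformer:::ad_smul(t, x, 2.5), A)
  num_grad_check(function(t, x)
    chemformer:::ad_layernorm(t, x, cc(t, G), cc(t, B)), A)
  num_grad_check(function(t, x) chemformer:::ad_pairsqdist(t, x),
                 matrix(rnorm(12), 4, 3))
})

test_that("nested op calls keep the tape topologically ordered", {
  # regression guard: an op used directly as another op's argument must
  # claim its id before the outer op does
  set.seed(3)
  A <- matrix(rnorm(20), 5, 4)
  W1 <- matrix(rnorm(16), 4, 4); W2 <- matrix(rnorm(16), 4, 4)
  cc <- chemformer:::ad_const
  num_grad_check(function(t, x) {
    chemformer:::ad_mm(t, chemformer:::ad_softmax_rows(t,
      chemformer:::ad_mm(t, x, cc(t, W1))),
      chemformer:::ad_transpose(t, chemformer:::ad_mm(t, x, cc(t, W2))))
  }, A)
})

test_that("masked loss gradients are exact and ignore missing labels", {
  set.seed(5)
  Z0 <- matrix(rnorm(4), 1)
  y <- matrix(c(1, 0, 1, 0), 1)
  mask <- matrix(c(1, 1, 0, 1), 1)
  for (lossop in list(chemformer:::ad_bce_logits, chemformer:::ad_mse)) {
    tape <- chemformer:::.tape_new()
    z <- chemformer:::ad_const(tape, Z0)
    tape$param_ids[["z"]] <- z
    l <- lossop(tape, z, y, mask)
    g <- chemformer:::ad_backward(tape, l)$z
    expect_equal(g[1, 3], 0)             # masked entry gets no gradient
    for (i in c(1, 2, 4)) {
      Zp <- Z0; eps <- 1e-6
      lv <- function(Zi) {
        t2 <- chemformer:::.tape_new()
        chemformer:::.val(t2, lossop(t2, chemformer:::ad_const(t2, Zi), y, mask))[1, 1]
      }
      Zp[i] <- Zp[i] + eps; lp <- lv(Zp)
      Zp[i] <- Zp[i] - 2 * eps; lm <- lv(Zp)
      expect_equal(g[1, i], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("Adam minimizes a simple quadratic", {
  params <- list(w = matrix(c(3, -2), 1))
  opt <- chemformer:::.adam_new()
  for (i in 1:600) {
    g <- list(w = 2 * params$w)        # d/dw ||w||^2
    params <- chemformer:::.adam_step(opt, params, g, lr = 0.05)
  }
  expect_lt(max(abs(params$w)), 1e-3)
})
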