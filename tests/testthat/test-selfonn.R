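# The generative-neuron layer: vectorized forward against the nested-loop
# oracle, degenerate cases, and gradients.

test_that("q = 1 degenerates to a plain convolution", {
  set.seed(101)
  spec <- selfonn_spec(2, 3, 5, q = 1)
  par <- selfonn_init(spec, seed = 1)
  x <- matrix(rnorm(2 * 30), 2, 30)
  # direct "same"-padded cross-correlation written independently
  ref <- matrix(0, 3, 30)
  xp <- cbind(matrix(0, 2, 2), x, matrix(0, 2, 2))
  for (o in 1:3) for (j in 1:30) {
    acc <- par$bias[o]
    for (c in 1:2) for (t in 1:5)
      acc <- acc + par$weights[1, o, c, t] * xp[c, j + t - 1]
    ref[o, j] <- acc
  }
  expect_lt(max(abs(selfonn_forward(x, spec, par) - ref)), 1e-6)
})

test_that("kernel-1 polynomial evaluates the Taylor form directly", {
  spec <- selfonn_spec(1, 1, 1, q = 3)
  par <- list(weights = array(1, c(3, 1, 1, 1)), bias = 0)
  # f(2) = 0 + 2 + 4 + 8
  expect_equal(selfonn_forward(matrix(2, 1, 1), spec, par)[1, 1], 14)
})

test_that("hand-expanded q = 2, kernel 3 case matches the oracle", {
  spec <- selfonn_spec(1, 1, 3, q = 2)
  w <- array(0, c(2, 1, 1, 3))
  w[1, 1, 1, ] <- c(1, 0, 2)
  w[2, 1, 1, ] <- c(0.5, 1, -1)
  par <- list(weights = w, bias = 0.5)
  x <- matrix(c(1, 2, 0, -1, 3), 1, 5)
  expected <- matrix(c(1.5, 6.0, 1.5, -1.5, 9.0), 1, 5)
  expect_equal(selfonn_oracle(x, spec, par), expected)
  expect_equal(selfonn_forward(x, spec, par), expected, tolerance = 1e-12)
})

test_that("oracle on all-zero input returns the broadcast bias", {
  spec <- selfonn_spec(2, 3, 5, q = 3)
  par <- selfonn_init(spec, seed = 2)
  y <- selfonn_oracle(matrix(0, 2, 20), spec, par)
  expect_equal(y, matrix(par$bias, 3, 20))
})

test_that("vectorized forward equals the nested-loop oracle on random cases", {
  set.seed(7)
  for (i in 1:50) {
    C <- sample(1:3, 1); O <- sample(1:3, 1)
    K <- sample(c(1, 3, 5), 1); q <- sample(1:3, 1)
    L <- sample(8:24, 1)
    spec <- selfonn_spec(C, O, K, q = q)
    par <- selfonn_init(spec)
    x <- matrix(rnorm(C * L), C, L)
    expect_lt(max(abs(selfonn_forward(x, spec, par) -
                      selfonn_oracle(x, spec, par))), 1e-5)
  }
})

test_that("contributions are additive across powers", {
  set.seed(8)
  spec <- selfonn_spec(2, 2, 3, q = 3)
  par <- selfonn_init(spec, seed = 3)
  x <- matrix(rnorm(2 * 16), 2, 16)
  total <- selfonn_forward(x, spec, par)
  parts <- lapply(1:3, function(k) {
    pk <- par
    pk$weights[setdiff(1:3, k), , , ] <- 0
    pk$bias <- par$bias * 0
    selfonn_forward(x, spec, pk)
  })
  expect_lt(max(abs(total - (parts[[1]] + parts[[2]] + parts[[3]] +
                             matrix(par$bias, 2, 16)))), 1e-6)
})

test_that("analytic layer gradients match finite differences", {
  set.seed(9)
  C <- 2; O <- 2; K <- 3; q <- 3; L <- 12; B <- 2
  spec <- selfonn_spec(C, O, K, q = q)
  par <- selfonn_init(spec, seed = 4)
  W <- mhdnet:::w4_to_mat(par$weights)
  x <- array(rnorm(C * L * B) * 0.5, c(C, L, B))
  tgt <- array(rnorm(O * L * B), c(O, L, B))
  lossv <- function(Wm, bm, xm) {
    y <- mhdnet:::selfonn_conv_fwd_cpp(xm, Wm, bm, q, K)
    0.5 * sum((y - tgt)^2)
  }
  y <- mhdnet:::selfonn_conv_fwd_cpp(x, W, par$bias, q, K)
  g <- mhdnet:::selfonn_conv_bwd_cpp(x, W, y - tgt, q, K)
  eps <- 1e-6
  for (i in sample(length(W), 8)) {
    W1 <- W; W1[i] <- W1[i] + eps
    W2 <- W; W2[i] <- W2[i] - eps
    fd <- (lossv(W1, par$bias, x) - lossv(W2, par$bias, x)) / (2 * eps)
    expect_lt(abs(fd - g$dW[i]) / max(abs(fd), abs(g$dW[i]), 1e-6), 1e-4)
  }
  for (i in sample(length(x), 8)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    fd <- (lossv(W, par$bias, x1) - lossv(W, par$bias, x2)) / (2 * eps)
    expect_lt(abs(fd - g$dX[i]) / max(abs(fd), abs(g$dX[i]), 1e-6), 1e-4)
  }
  for (i in seq_len(O)) {
    b1 <- par$bias; b1[i] <- b1[i] + eps
    b2 <- par$bias; b2[i] <- b2[i] - eps
    fd <- (lossv(W, b1, x) - lossv(W, b2, x)) / (2 * eps)
    expect_lt(abs(fd - g$db[i]) / max(abs(fd), abs(g$db[i]), 1e-6), 1e-4)
  }
})

test_that("a Self-ONN layer followed by tanh is bounded in (-1, 1)", {
  set.seed(10)
  spec <- selfonn_spec(3, 4, 11, q = 3)
  par <- selfonn_init(spec, seed = 5)
  x <- matrix(rnorm(3 * 100), 3, 100)
  y <- tanh(selfonn_forward(x, spec, par))
  expect_true(all(y > -1 & y < 1))
  # even wild inputs cannot escape the bound
  yw <- tanh(selfonn_forward(x * 20, spec, par))
  expect_true(all(yw >= -1 & yw <= 1))
})

test_that("spec/parameter shape mismatches raise contract errors", {
  spec <- selfonn_spec(2, 3, 5, q = 2)
  par <- selfonn_init(selfonn_spec(2, 3, 5, q = 3), seed = 1)
  x <- matrix(rnorm(2 * 20), 2, 20)
  expect_error(selfonn_forward(x, spec, par), class = "mhdnet_contract_error")
  good <- selfonn_init(spec, seed = 1)
  expect_error(selfonn_forward(matrix(0, 3, 20), spec, good),
               class = "mhdnet_contract_error")
})
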