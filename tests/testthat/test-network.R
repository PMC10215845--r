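# Architecture assembly: shape contracts, attention gate, variants, parameter
# count, and end-to-end differentiability of the assembled network.

small_cfg <- function(...) mhdnet_config(levels = 2, base_filters = 4, ...)

test_that("output length equals input length across window sizes", {
  cfg <- mhdnet_config(levels = 4, base_filters = 2, kernel_size = 11)
  par <- mhdnet_init(cfg, seed = 1)
  for (L in c(2048, 4096, 8192)) {
    y <- mhdnet_forward(matrix(rnorm(3 * L), 3, L), cfg, par)
    expect_length(y, L)
    expect_true(all(is.finite(y)))
  }
})

test_that("indivisible lengths raise a shape error naming the divisor", {
  cfg <- mhdnet_config(levels = 4, base_filters = 2)
  par <- mhdnet_init(cfg, seed = 1)
  expect_error(mhdnet_forward(matrix(0, 3, 4095), cfg, par),
               "16", class = "mhdnet_shape_error")
})

test_that("attention gate multiplies the encoder signal by a (0,1) gate", {
  cfg <- mhdnet_config(levels = 2, base_filters = 16)
  par <- mhdnet_init(cfg, seed = 2)
  ap <- par$att[[1]]
  enc <- matrix(rnorm(16 * 4096), 16, 4096)
  dec <- matrix(rnorm(32 * 2048), 32, 2048)
  out <- attention_gate(enc, dec, ap)
  expect_equal(dim(out), c(16, 4096))
  expect_true(all(abs(out) <= abs(enc)))
  expect_equal(attention_gate(enc * 0, dec, ap), enc * 0)
  expect_error(attention_gate(enc, dec[, 1:1000], ap),
               class = "mhdnet_contract_error")
})

test_that("parameter count matches an independent closed-form tally", {
  tally <- function(lv, bf, K, q, att, cin = 3, cout = 1) {
    filt <- bf * 2^(seq_len(lv) - 1)
    conv <- function(ci, co, k) q * ci * k * co + co
    norm <- function(c) 2 * c
    n <- 0
    for (i in seq_len(lv)) {
      ci <- if (i == 1) cin else filt[i - 1]
      n <- n + conv(ci, filt[i], K) + norm(filt[i])
    }
    n <- n + conv(filt[lv], 2 * filt[lv], K) + norm(2 * filt[lv])
    for (i in seq_len(lv))
      n <- n + conv(3 * filt[i], filt[i], K) + norm(filt[i])
    if (att) for (i in seq_len(lv)) {
      C <- filt[i]
      n <- n + conv(C, C, 1) + norm(C) +       # encoder branch
        conv(2 * C, C, 1) + norm(C) +          # decoder branch
        conv(C, 1, 1) + norm(1)                # gate head
    }
    n + conv(sum(filt[seq_len(min(3, lv))]), cout, 1)
  }
  for (cfg in list(mhdnet_config(),                       # default model
                   mhdnet_config(levels = 2, base_filters = 8),
                   build_variant("fpn_cnn", levels = 3, base_filters = 4))) {
    expect_equal(count_params(mhdnet_init(cfg, seed = 1)),
                 tally(cfg$levels, cfg$base_filters, cfg$kernel_size,
                       cfg$q, cfg$use_attention, cfg$in_channels,
                       cfg$out_channels))
  }
})

test_that("ablation variants wire the documented mechanisms", {
  v <- build_variant("self_fpn")
  expect_false(v$use_attention)
  expect_identical(v$layer_kind, "selfonn")
  expect_equal(v$q, 3)
  c <- build_variant("fpn_cnn")
  expect_equal(c$q, 1)
  expect_identical(c$activation, "relu")
  full <- build_variant("self_attention_mhdnet")
  expect_identical(unclass(full), unclass(mhdnet_config()))
  expect_error(build_variant("resnet"), class = "mhdnet_value_error")
})

test_that("variants without attention still run (ablation parity)", {
  for (v in c("fpn_cnn", "self_fpn")) {
    cfg <- build_variant(v, levels = 2, base_filters = 4)
    par <- mhdnet_init(cfg, seed = 3)
    y <- mhdnet_forward(matrix(rnorm(3 * 1024), 3, 1024), cfg, par)
    expect_length(y, 1024)
  }
})

test_that("forward is deterministic given parameters", {
  cfg <- small_cfg()
  par <- mhdnet_init(cfg, seed = 4)
  x <- matrix(rnorm(3 * 1024), 3, 1024)
  expect_identical(mhdnet_forward(x, cfg, par), mhdnet_forward(x, cfg, par))
})

test_that("bottleneck filters follow the doubling schedule", {
  expect_equal(mhdnet_config()$bottleneck_filters, 256)
  expect_equal(mhdnet_config(levels = 2, base_filters = 8)$bottleneck_filters,
               32)
})

test_that("whole-network gradients match finite differences", {
  set.seed(31)
  cfg <- mhdnet_config(levels = 2, base_filters = 2, kernel_size = 3, q = 2)
  par <- mhdnet_init(cfg, seed = 5)
  L <- 32; B <- 2
  x <- array(rnorm(3 * L * B), c(3, L, B))
  y <- matrix(rbinom(L * B, 1, 0.1), L, B)
  lossf <- function(p) {
    z <- matrix(mhdnet:::net_fwd(x, cfg, p)$logits[1, , ], L, B)
    mhdnet:::bce_with_logits(z, y)$loss
  }
  fw <- mhdnet:::net_fwd(x, cfg, par, keep = TRUE)
  bl <- mhdnet:::bce_with_logits(matrix(fw$logits[1, , ], L, B), y)
  g <- mhdnet:::net_bwd(array(bl$dz, c(1, L, B)), cfg, par, fw$cache)
  get_leaf <- function(o, path) { for (k in path) o <- o[[k]]; o }
  set_leaf <- function(o, path, v) {
    if (length(path) == 1) { o[[path[[1]]]] <- v; return(o) }
    o[[path[[1]]]] <- set_leaf(o[[path[[1]]]], path[-1], v)
    o
  }
  paths <- list(list("enc", 1L, "conv", "W"), list("enc", 2L, "norm", "gamma"),
                list("dec", 1L, "conv", "W"), list("dec", 2L, "norm", "beta"),
                list("att", 1L, "phi_conv", "W"),
                list("att", 2L, "theta_conv", "W"),
                list("att", 1L, "psi_norm", "gamma"),
                list("bott", "conv", "W"), list("head", "conv", "W"))
  eps <- 1e-5
  for (pth in paths) {
    leaf <- get_leaf(par, pth)
    ga <- get_leaf(g, pth)
    for (i in sample(length(leaf), min(3, length(leaf)))) {
      l1 <- leaf; l1[i] <- l1[i] + eps
      l2 <- leaf; l2[i] <- l2[i] - eps
      fd <- (lossf(set_leaf(par, pth, l1)) - lossf(set_leaf(par, pth, l2))) /
        (2 * eps)
      expect_lt(abs(fd - ga[i]) / max(abs(fd), abs(ga[i]), 1e-6), 1e-3)
    }
  }
})
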