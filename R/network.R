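#' Architecture configuration for the R-peak segmentation network
#'
#' The network is a 1D encoder/decoder: each encoder level is one operational
#' block (Self-ONN convolution, instance normalization, activation) followed by
#' max-pooling by 2; the bottleneck doubles the deepest filter count; each
#' decoder level upsamples by 2, concatenates the (optionally attention-gated)
#' encoder skip, and applies one operational block.  The output head fuses the
#' feature maps of decoder levels 1-3 (interpolated to full length) and maps
#' them to per-sample logits with a kernel-1 operational layer.
#'
#' Filter counts double with depth: level `i` has `base_filters * 2^(i-1)`
#' channels and the bottleneck has `base_filters * 2^levels` (so the defaults
#' give 16, 32, 64, 128 with a 256-filter bottleneck).
#'
#' @param levels Number of encoder/decoder levels.
#' @param base_filters Filters in the first encoder level.
#' @param kernel_size Kernel length used throughout (odd).
#' @param q Polynomial order of the generative neurons.
#' @param use_attention Gate the skip connections with learned attention.
#' @param layer_kind `"selfonn"` or `"cnn"` (the `q = 1` degenerate).
#' @param activation Block activation, `"tanh"` (Self-ONN) or `"relu"` (CNN).
#' @param in_channels,out_channels Signal channels in, mask channels out.
#' @return Object of class `mhdnet_config`.
#' @export
mhdnet_config <- function(levels = 4, base_filters = 16, kernel_size = 11,
                          q = 3, use_attention = TRUE,
                          layer_kind = c("selfonn", "cnn"),
                          activation = c("tanh", "relu"),
                          in_channels = 3, out_channels = 1) {
  layer_kind <- match.arg(layer_kind)
  activation <- match.arg(activation)
  if (levels < 1) stop_value("levels must be >= 1")
  if (kernel_size %% 2 != 1) stop_value("kernel_size must be odd")
  if (layer_kind == "cnn" && q != 1) q <- 1L
  structure(
    list(levels = as.integer(levels),
         base_filters = as.integer(base_filters),
         bottleneck_filters = as.integer(base_filters * 2^levels),
         kernel_size = as.integer(kernel_size),
         q = as.integer(q),
         use_attention = isTRUE(use_attention),
         layer_kind = layer_kind,
         activation = activation,
         in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels)),
    class = "mhdnet_config"
  )
}

#' @export
print.mhdnet_config <- function(x, ...) {
  filt <- x$base_filters * 2^(seq_len(x$levels) - 1)
  cat(sprintf(
    "mhdnet_config: %s (q=%d), %d levels [%s] + bottleneck %d, kernel %d,\n  activation %s, attention %s, %d -> %d channels\n",
    x$layer_kind, x$q, x$levels, paste(filt, collapse = ", "),
    x$bottleneck_filters, x$kernel_size, x$activation,
    if (x$use_attention) "on" else "off", x$in_channels, x$out_channels))
  invisible(x)
}

#' Named architecture variants for the ablation study
#'
#' * `fpn_cnn` - plain convolutional FPN baseline: `q` forced to 1, ReLU
#'   activations, no attention gates.
#' * `self_fpn` - Self-ONN layers (`q = 3`, tanh) without attention.
#' * `self_attention_mhdnet` - the full model: Self-ONN layers with
#'   attention-gated skips.
#'
#' All other hyperparameters are shared, so the variants differ only in the
#' mechanisms under ablation.
#'
#' @param name Variant name.
#' @param ... Overrides passed to [mhdnet_config()] (e.g. `levels`,
#'   `base_filters`) applied identically to every variant.
#' @return An `mhdnet_config`.
#' @export
build_variant <- function(name = c("self_attention_mhdnet", "self_fpn",
                                   "fpn_cnn"), ...) {
  if (length(name) != 1 || !name %in% c("self_attention_mhdnet", "self_fpn",
                                        "fpn_cnn"))
    stop_value(sprintf("unknown variant '%s'", paste(name, collapse = ",")))
  switch(name,
    fpn_cnn = mhdnet_config(..., q = 1, use_attention = FALSE,
                            layer_kind = "cnn", activation = "relu"),
    self_fpn = mhdnet_config(..., use_attention = FALSE,
                             layer_kind = "selfonn", activation = "tanh"),
    self_attention_mhdnet = mhdnet_config(..., use_attention = TRUE,
                                          layer_kind = "selfonn",
                                          activation = "tanh"))
}

# Internal conv-layer constructor storing the flattened weight layout; meta
# lives in an attribute so parameter-tree walks see only learnable leaves.
new_conv <- function(C, O, K, q) {
  sdw <- sqrt(1 / (C * K))
  w4 <- array(rnorm(q * O * C * K, sd = sdw), c(q, O, C, K))
  for (k in seq_len(q)) w4[k, , , ] <- w4[k, , , ] / factorial(k)
  structure(list(W = w4_to_mat(w4), b = numeric(O)),
            meta = c(C = C, O = O, K = K, q = q))
}

new_norm <- function(C) list(gamma = rep(1, C), beta = numeric(C))

net_conv_fwd <- function(x, layer) {
  m <- attr(layer, "meta")
  selfonn_conv_fwd_cpp(x, layer$W, layer$b, m[["q"]], m[["K"]])
}

net_conv_bwd <- function(dy, x, layer) {
  m <- attr(layer, "meta")
  g <- selfonn_conv_bwd_cpp(x, layer$W, dy, m[["q"]], m[["K"]])
  list(dx = g$dX, grads = list(W = g$dW, b = as.numeric(g$db)))
}

#' Initialize the parameter collection for a network configuration
#'
#' @param config An [mhdnet_config()].
#' @param seed Optional seed for a deterministic draw (caller RNG untouched).
#' @return Nested parameter list (class `mhdnet_params`); layer shapes are
#'   fully determined by `config`.
#' @export
mhdnet_init <- function(config, seed = NULL) {
  build <- function() {
    lv <- config$levels
    filt <- config$base_filters * 2^(seq_len(lv) - 1)
    K <- config$kernel_size; q <- config$q
    p <- list()
    p$enc <- lapply(seq_len(lv), function(i) {
      cin <- if (i == 1) config$in_channels else filt[i - 1]
      list(conv = new_conv(cin, filt[i], K, q), norm = new_norm(filt[i]))
    })
    p$bott <- list(conv = new_conv(filt[lv], config$bottleneck_filters, K, q),
                   norm = new_norm(config$bottleneck_filters))
    p$dec <- lapply(seq_len(lv), function(i) {
      list(conv = new_conv(3 * filt[i], filt[i], K, q),
           norm = new_norm(filt[i]))
    })
    if (config$use_attention) {
      p$att <- lapply(seq_len(lv), function(i) {
        C <- filt[i]
        list(phi_conv = new_conv(C, C, 1, q), phi_norm = new_norm(C),
             theta_conv = new_conv(2 * C, C, 1, q), theta_norm = new_norm(C),
             psi_conv = new_conv(C, 1, 1, q), psi_norm = new_norm(1))
      })
    }
    nhead <- sum(filt[seq_len(min(3, lv))])
    p$head <- list(conv = new_conv(nhead, config$out_channels, 1, q))
    structure(p, class = "mhdnet_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Total number of learnable parameters
#'
#' @param params An `mhdnet_params` tree (or any nested list of arrays).
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(params) {
  as.integer(ptree_sum(length, unclass(params)))
}

# ---- attention gate --------------------------------------------------------
# enc: [C, L, B] skip signal; dec: [2C, L/2, B] coarser decoder signal.
# Both are projected to C channels by kernel-1 operational layers + instance
# norm; the decoder branch is upsampled x2; their sum passes tanh, then a
# kernel-1 layer to one channel + instance norm + sigmoid yields the gate,
# which multiplies the encoder signal elementwise.

att_fwd <- function(enc, dec, ap) {
  C <- dim(enc)[1]; L <- dim(enc)[2]; B <- dim(enc)[3]
  if (dim(dec)[2] * 2 != L)
    stop_contract(sprintf(
      "decoder signal length %d is not half the encoder length %d",
      dim(dec)[2], L))
  if (dim(dec)[1] != 2 * C)
    stop_contract(sprintf("decoder signal has %d channels, expected %d",
                          dim(dec)[1], 2 * C))
  a0 <- net_conv_fwd(enc, ap$phi_conv)
  an <- inorm_fwd(a0, ap$phi_norm$gamma, ap$phi_norm$beta)
  t0 <- net_conv_fwd(dec, ap$theta_conv)
  tn <- inorm_fwd(t0, ap$theta_norm$gamma, ap$theta_norm$beta)
  tu <- upsample_fwd(tn$y)
  s <- tanh(an$y + tu)
  p0 <- net_conv_fwd(s, ap$psi_conv)
  pn <- inorm_fwd(p0, ap$psi_norm$gamma, ap$psi_norm$beta)
  g <- sigmoid(pn$y)                                   # [1, L, B]
  ge <- array(rep(as.numeric(g[1, , ]), each = C), c(C, L, B))
  list(y = enc * ge,
       cache = list(enc = enc, dec = dec, s = s, g = g, ge = ge,
                    an = an$cache, tn = tn$cache, pn = pn$cache))
}

att_bwd <- function(dy, cache, ap) {
  C <- dim(cache$enc)[1]; L <- dim(cache$enc)[2]; B <- dim(cache$enc)[3]
  denc <- dy * cache$ge
  dg <- array(colSums(dy * cache$enc), c(1, L, B))
  dpn <- dg * cache$g * (1 - cache$g)
  pb <- inorm_bwd(dpn, cache$pn, ap$psi_norm$gamma)
  pc <- net_conv_bwd(pb$dx, cache$s, ap$psi_conv)
  ds <- pc$dx * (1 - cache$s * cache$s)
  ab <- inorm_bwd(ds, cache$an, ap$phi_norm$gamma)
  ac <- net_conv_bwd(ab$dx, cache$enc, ap$phi_conv)
  denc <- denc + ac$dx
  dtu <- upsample_bwd(ds)
  tb <- inorm_bwd(dtu, cache$tn, ap$theta_norm$gamma)
  tc <- net_conv_bwd(tb$dx, cache$dec, ap$theta_conv)
  list(denc = denc, ddec = tc$dx,
       grads = list(phi_conv = ac$grads,
                    phi_norm = list(gamma = ab$dgamma, beta = ab$dbeta),
                    theta_conv = tc$grads,
                    theta_norm = list(gamma = tb$dgamma, beta = tb$dbeta),
                    psi_conv = pc$grads,
                    psi_norm = list(gamma = pb$dgamma, beta = pb$dbeta)))
}

#' Attention gate over a skip connection
#'
#' Computes a learned multiplicative gate in (0, 1) from the encoder signal at
#' level *i* and the coarser decoder signal at level *i + 1*, and applies it to
#' the encoder signal.  The gate is broadcast over channels, so
#' `|output| <= |enc|` elementwise.
#'
#' @param enc Encoder signal, matrix `[C, L]` or array `[C, L, B]`.
#' @param dec Decoder signal, matrix `[2C, L/2]` or array `[2C, L/2, B]`.
#' @param params Gate parameter block (one element of `mhdnet_params$att`).
#' @return Gated signal with the shape of `enc`.
#' @export
attention_gate <- function(enc, dec, params) {
  was_mat <- is.matrix(enc)
  out <- att_fwd(as_cube(enc), as_cube(dec), params)$y
  if (was_mat) matrix(out, nrow = dim(out)[1]) else out
}

# ---- full network ----------------------------------------------------------

net_fwd <- function(x, config, params, keep = FALSE) {
  lv <- config$levels
  filt <- config$base_filters * 2^(seq_len(lv) - 1)
  act <- config$activation
  L <- dim(x)[2]
  if (L %% 2^lv != 0)
    stop_shape(sprintf("input length %d is not divisible by %d (2^levels)",
                       L, 2^lv))
  if (L < 2^lv * config$kernel_size)
    stop_shape(sprintf("input length %d shorter than 2^levels * kernel = %d",
                       L, 2^lv * config$kernel_size))
  if (dim(x)[1] != config$in_channels)
    stop_shape(sprintf("input has %d channels, config requires %d",
                       dim(x)[1], config$in_channels))

  block_fwd <- function(x, lp) {
    y0 <- net_conv_fwd(x, lp$conv)
    nn <- inorm_fwd(y0, lp$norm$gamma, lp$norm$beta)
    av <- act_fwd(nn$y, act)
    list(y = av$y, cache = list(x = x, norm = nn$cache, act = av$cache))
  }

  enc_cache <- vector("list", lv)
  enc_act <- vector("list", lv)
  pool_mask <- vector("list", lv)
  cur <- x
  for (i in seq_len(lv)) {
    bf <- block_fwd(cur, params$enc[[i]])
    enc_act[[i]] <- bf$y
    enc_cache[[i]] <- bf$cache
    mp <- maxpool_fwd(bf$y)
    pool_mask[[i]] <- mp$cache
    cur <- mp$y
  }
  bb <- block_fwd(cur, params$bott)
  bott_cache <- bb$cache

  dec_out <- vector("list", lv)
  dec_cache <- vector("list", lv)
  att_cache <- vector("list", lv)
  deeper <- bb$y
  for (i in rev(seq_len(lv))) {
    up <- upsample_fwd(deeper)
    if (config$use_attention) {
      af <- att_fwd(enc_act[[i]], deeper, params$att[[i]])
      skip <- af$y
      att_cache[[i]] <- af$cache
    } else skip <- enc_act[[i]]
    cat_in <- chan_cat(up, skip)
    df <- block_fwd(cat_in, params$dec[[i]])
    dec_out[[i]] <- df$y
    dec_cache[[i]] <- df$cache
    deeper <- df$y
  }

  nh <- min(3, lv)
  maps <- vector("list", nh)
  for (i in seq_len(nh)) {
    m <- dec_out[[i]]
    if (i > 1) for (r in seq_len(i - 1)) m <- upsample_fwd(m)
    maps[[i]] <- m
  }
  head_in <- maps[[1]]
  if (nh > 1) for (i in 2:nh) head_in <- chan_cat(head_in, maps[[i]])
  logits <- net_conv_fwd(head_in, params$head$conv)   # [out_channels, L, B]

  cache <- if (keep)
    list(enc = enc_cache, pool = pool_mask, bott = bott_cache,
         dec = dec_cache, att = att_cache, head_in = head_in,
         filt = filt, nh = nh)
  else NULL
  list(logits = logits, cache = cache)
}

net_bwd <- function(dlogits, config, params, cache) {
  lv <- config$levels
  filt <- cache$filt
  act <- config$activation
  g <- ptree_map(function(a) a * 0, unclass(params))

  block_bwd <- function(dy, bc, lp) {
    da <- act_bwd(dy, bc$act, act)
    nb <- inorm_bwd(da, bc$norm, lp$norm$gamma)
    cb <- net_conv_bwd(nb$dx, bc$x, lp$conv)
    list(dx = cb$dx,
         grads = list(conv = cb$grads,
                      norm = list(gamma = nb$dgamma, beta = nb$dbeta)))
  }

  # head
  hb <- net_conv_bwd(dlogits, cache$head_in, params$head$conv)
  g$head$conv <- hb$grads
  nh <- cache$nh
  ddec <- vector("list", lv + 1)          # grads w.r.t. decoder outputs
  off <- 0
  for (i in seq_len(nh)) {
    dm <- hb$dx[off + seq_len(filt[i]), , , drop = FALSE]
    off <- off + filt[i]
    if (i > 1) for (r in seq_len(i - 1)) dm <- upsample_bwd(dm)
    ddec[[i]] <- dm
  }

  denc_skip <- vector("list", lv)         # grads flowing into encoder acts
  for (i in seq_len(lv)) {
    db <- block_bwd(ddec[[i]], cache$dec[[i]], params$dec[[i]])
    g$dec[[i]] <- db$grads
    nup <- 2 * filt[i]
    dup <- db$dx[seq_len(nup), , , drop = FALSE]
    dskip <- db$dx[nup + seq_len(filt[i]), , , drop = FALSE]
    ddeep <- upsample_bwd(dup)
    if (config$use_attention) {
      ab <- att_bwd(dskip, cache$att[[i]], params$att[[i]])
      g$att[[i]] <- ab$grads
      denc_skip[[i]] <- ab$denc
      ddeep <- ddeep + ab$ddec
    } else denc_skip[[i]] <- dskip
    if (is.null(ddec[[i + 1]])) ddec[[i + 1]] <- ddeep
    else ddec[[i + 1]] <- ddec[[i + 1]] + ddeep
  }

  bb <- block_bwd(ddec[[lv + 1]], cache$bott, params$bott)
  g$bott <- bb$grads
  dpool <- bb$dx
  for (i in rev(seq_len(lv))) {
    da <- maxpool_bwd(dpool, cache$pool[[i]]) + denc_skip[[i]]
    eb <- block_bwd(da, cache$enc[[i]], params$enc[[i]])
    g$enc[[i]] <- eb$grads
    dpool <- eb$dx
  }
  g
}

#' Forward pass of the segmentation network
#'
#' Maps a (preprocessed, per-channel standardized) multichannel ECG segment to
#' per-sample mask logits.  The input length must be divisible by
#' `2^levels`; the output has exactly the input length.
#'
#' @param x Segment, matrix `[in_channels, L]` or array `[in_channels, L, B]`.
#' @param config An [mhdnet_config()].
#' @param params Parameters from [mhdnet_init()] or a fitted model.
#' @return Numeric vector of logits (length `L`), or an `[L, B]` matrix for
#'   batched input.
#' @export
mhdnet_forward <- function(x, config, params) {
  was_mat <- is.matrix(x) || is.null(dim(x))
  out <- net_fwd(as_cube(x), config, params)$logits
  if (was_mat) as.numeric(out[1, , 1])
  else matrix(out[1, , ], nrow = dim(out)[2])
}
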