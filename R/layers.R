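# Pure-R layer primitives operating on [C, L, B] arrays (channels x length x
# batch).  Each *_fwd returns list(y, cache); each *_bwd consumes the cache and
# the upstream gradient and returns gradients w.r.t. inputs (and parameters
# where the layer has them).

# ---- instance normalization (per channel, per sample) ----------------------

inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- inorm_fwd_cpp(x, gamma, beta, eps)
  list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd))
}

inorm_bwd <- function(dy, cache, gamma) {
  inorm_bwd_cpp(dy, cache$xhat, cache$istd, gamma)
}

# ---- activations -----------------------------------------------------------

act_fwd <- function(x, kind) {
  y <- switch(kind,
    tanh = tanh(x),
    relu = pmax(x, 0),
    sigmoid = sigmoid(x),
    stop_value(sprintf("unknown activation '%s'", kind))
  )
  list(y = y, cache = y)
}

act_bwd <- function(dy, y, kind) {
  switch(kind,
    tanh = dy * (1 - y * y),
    relu = dy * (y > 0),
    sigmoid = dy * y * (1 - y)
  )
}

# ---- max pooling / upsampling by 2 (compiled kernels) ----------------------

maxpool_fwd <- function(x) {
  r <- maxpool_fwd_cpp(x)
  list(y = r$y, cache = r$left)
}

maxpool_bwd <- function(dy, left) maxpool_bwd_cpp(dy, left)

upsample_fwd <- function(x) upsample_fwd_cpp(x)

upsample_bwd <- function(dy) upsample_bwd_cpp(dy)

# ---- binary cross-entropy on logits ----------------------------------------
# loss_i = w_pos * y_i * softplus(-z_i) + (1 - y_i) * softplus(z_i), averaged.

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

bce_with_logits <- function(z, y, pos_weight = 1) {
  n <- length(z)
  loss <- sum(pos_weight * y * softplus(-z) + (1 - y) * softplus(z)) / n
  dz <- (-pos_weight * y * sigmoid(-z) + (1 - y) * sigmoid(z)) / n
  list(loss = loss, dz = dz)
}
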