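#' Specification of a 1D self-organizing operational (Self-ONN) layer
#'
#' A generative neuron replaces the convolution kernel's linear response with a
#' learnable polynomial of order `q`: the layer output is
#' `b + w1 * x + w2 * x^2 + ... + wq * x^q`, where `x^k` is the elementwise
#' k-th power of the input and each `wk` is a full cross-correlation kernel
#' bank.  With `q = 1` the layer degenerates to an ordinary convolution.
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel_size Odd kernel length, so "same" zero padding preserves the
#'   signal length.
#' @param q Polynomial order of the generative neuron (`q >= 1`).
#' @param padding Zero padding on each side; defaults to `(kernel_size - 1)/2`.
#' @return An object of class `selfonn_spec`.
#' @seealso [selfonn_init()], [selfonn_forward()], [selfonn_oracle()]
#' @export
selfonn_spec <- function(in_channels, out_channels, kernel_size, q = 3,
                         padding = (kernel_size - 1) / 2) {
  if (q < 1) stop_value("q must be >= 1")
  if (kernel_size %% 2 != 1) stop_value("kernel_size must be odd")
  structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         kernel_size = as.integer(kernel_size),
         q = as.integer(q),
         padding = as.integer(padding)),
    class = "selfonn_spec"
  )
}

#' Initialize parameters for a Self-ONN layer
#'
#' Variance-scaled initialization applied independently per power bank; banks
#' for powers `k >= 2` are shrunk by `1/k!` so that, at initialization, the
#' polynomial response mirrors a Taylor expansion dominated by its linear term
#' and activations stay in the quasi-linear range of `tanh`.
#'
#' @param spec A [selfonn_spec()].
#' @param seed Optional integer seed; when given the draw is deterministic and
#'   the caller's RNG state is untouched.
#' @return List with `weights` (array `[q, out, in, kernel]`) and `bias`
#'   (length `out`).
#' @export
selfonn_init <- function(spec, seed = NULL) {
  C <- spec$in_channels; O <- spec$out_channels
  K <- spec$kernel_size; q <- spec$q
  draw <- function() {
    sdw <- sqrt(1 / (C * K))
    w <- array(rnorm(q * O * C * K, sd = sdw), c(q, O, C, K))
    for (k in seq_len(q)) w[k, , , ] <- w[k, , , ] / factorial(k)
    list(weights = w, bias = numeric(O))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Flatten the public [q, O, C, K] weight array into the [O, K*q*C] matrix the
# compiled kernels use (column index = (t-1)*q*C + (k-1)*C + c: tap-major so
# each tap's [O, q*C] block is contiguous for the tap-sliced GEMMs).
w4_to_mat <- function(w4) {
  d <- dim(w4)  # q, O, C, K
  t(matrix(aperm(w4, c(3, 1, 4, 2)), d[3] * d[1] * d[4], d[2]))
}

mat_to_w4 <- function(W, q, C, K) {
  O <- nrow(W)
  aperm(array(t(W), c(C, q, K, O)), c(2, 4, 1, 3))
}

check_selfonn_shapes <- function(x, spec, params) {
  dw <- dim(params$weights)
  if (length(dw) != 4 ||
      dw[1] != spec$q || dw[2] != spec$out_channels ||
      dw[3] != spec$in_channels || dw[4] != spec$kernel_size)
    stop_contract(sprintf(
      "weights have shape [%s] but spec requires [q=%d, out=%d, in=%d, kernel=%d]",
      paste(dw, collapse = ", "), spec$q, spec$out_channels,
      spec$in_channels, spec$kernel_size))
  if (length(params$bias) != spec$out_channels)
    stop_contract("bias length does not match out_channels")
  if (nrow(x) != spec$in_channels)
    stop_contract(sprintf("input has %d channels, spec requires %d",
                          nrow(x), spec$in_channels))
  if (ncol(x) < spec$kernel_size)
    stop_contract("input shorter than the kernel")
  if (any(!is.finite(x))) stop_contract("input contains non-finite values")
}

#' Forward pass of a Self-ONN layer
#'
#' Computes `y[o] = bias[o] + sum_k crosscorrelate(x^k, weights[k, o, , ])`
#' with zero "same" padding, so the output length equals the input length.
#'
#' @param x Input matrix `[in_channels, L]`.
#' @param spec A [selfonn_spec()].
#' @param params Parameters as returned by [selfonn_init()].
#' @return Matrix `[out_channels, L]`.
#' @export
selfonn_forward <- function(x, spec, params) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  check_selfonn_shapes(x, spec, params)
  W <- w4_to_mat(params$weights)
  y <- selfonn_conv_fwd_cpp(array(x, c(dim(x), 1L)), W,
                            as.numeric(params$bias), spec$q, spec$kernel_size)
  matrix(y, nrow = spec$out_channels)
}

#' Brute-force reference implementation of the Self-ONN forward pass
#'
#' Explicit loops over output channels, positions, powers, input channels and
#' kernel taps, sharing no code with [selfonn_forward()].  Intended as a
#' verification twin; quadratic-time and only suitable for small inputs.
#'
#' @inheritParams selfonn_forward
#' @return Matrix `[out_channels, L]`.
#' @export
selfonn_oracle <- function(x, spec, params) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  check_selfonn_shapes(x, spec, params)
  C <- spec$in_channels; O <- spec$out_channels
  K <- spec$kernel_size; q <- spec$q
  pad <- spec$padding
  L <- ncol(x)
  y <- matrix(0, O, L)
  for (o in seq_len(O)) {
    for (j in seq_len(L)) {
      acc <- params$bias[o]
      for (k in seq_len(q)) {
        for (c in seq_len(C)) {
          for (t in seq_len(K)) {
            idx <- j + t - 1 - pad
            if (idx >= 1 && idx <= L)
              acc <- acc + params$weights[k, o, c, t] * x[c, idx]^k
          }
        }
      }
      y[o, j] <- acc
    }
  }
  y
}
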