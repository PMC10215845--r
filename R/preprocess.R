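#' Filter settings for MHD-corrupted ECG
#'
#' The cleaning chain is a 0.05-100 Hz bandpass (removing baseline wander
#' below 0.05 Hz and high-frequency noise above 100 Hz) followed by a narrow
#' notch at the 50 Hz powerline frequency.  Both are applied forward-backward
#' (zero phase) so that R-peak timing — which the labels and the tolerance
#' scoring depend on — is not shifted.
#'
#' @param low_cut_hz,high_cut_hz Bandpass corner frequencies in Hz.
#' @param notch_hz Powerline rejection frequency in Hz.
#' @param notch_q Notch quality factor (bandwidth = `notch_hz / notch_q`).
#' @param order Butterworth order for each bandpass half (high-pass and
#'   low-pass are cascaded rather than designed as one 2*order-pole bandpass,
#'   which is numerically fragile with a 0.05 Hz corner).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut_hz = 0.05, high_cut_hz = 100, notch_hz = 50,
                        notch_q = 30, order = 4) {
  if (low_cut_hz <= 0 || high_cut_hz <= low_cut_hz)
    stop_parameter("need 0 < low_cut_hz < high_cut_hz")
  if (notch_hz <= 0 || notch_q <= 0)
    stop_parameter("notch_hz and notch_q must be positive")
  if (order < 1) stop_parameter("order must be >= 1")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 notch_hz = notch_hz, notch_q = notch_q,
                 order = as.integer(order)),
            class = "filter_spec")
}

check_filter_pre <- function(x, fs, spec, f_top) {
  if (f_top >= fs / 2)
    stop_parameter(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                           f_top, fs / 2))
  if (length(x) <= 3 * spec$order)
    stop_parameter("signal too short for the filter order")
}

# Steady-state initial conditions (per unit input) for a direct-form-II-
# transposed IIR filter: under a constant input x the state recursion
# z[j-1] = b[j] x + z[j] - a[j] g x  (g = DC gain) telescopes to
# z[j] = x * sum_{k > j} (b[k] - a[k] g), which is exact even when poles sit
# arbitrarily close to z = 1 (a 0.05 Hz corner at 1024 Hz), where the usual
# (I - A') solve is numerically singular.  Seeding the delay line this way
# makes e.g. a high-pass respond to a constant with exactly zero from the
# first sample.
lfilter_zi <- function(b, a) {
  g <- sum(b) / sum(a)
  rev(cumsum(rev(b[-1] - a[-1] * g)))
}

# Zero-phase filtering: odd-extension padding at both ends plus steady-state
# initial conditions, then one forward and one reversed pass.  The pad must
# cover the filter's settling time, which for a 0.05 Hz corner runs to
# thousands of samples, so it is sized from the slowest pole (and capped at
# the signal length).
filtfilt_zi <- function(b, a, x) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  pmax_mod <- max(Mod(polyroot(rev(a))))
  tau <- if (pmax_mod >= 1) length(x) - 1 else -1 / log(pmax_mod)
  padlen <- min(length(x) - 1, max(3 * n, ceiling(3 * tau)))
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[padlen + seq_along(x)]
}

# Butterworth design as a cascade of second-order sections (bilinear biquads
# with the Butterworth Q ladder, plus a first-order section for odd orders).
# A monolithic direct-form polynomial of order 4 with a 0.05 Hz corner at
# 1024 Hz puts all poles within 1e-3 of z = 1 and its coefficient rounding
# visibly distorts the passband; the cascade keeps each section well
# conditioned.
butter_sections <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  w0 <- 2 * pi * fc / fs
  cw <- cos(w0); sw <- sin(w0)
  secs <- list()
  for (k in seq_len(order %/% 2)) {
    Q <- 1 / (2 * sin((2 * k - 1) * pi / (2 * order)))
    alpha <- sw / (2 * Q)
    a <- c(1 + alpha, -2 * cw, 1 - alpha)
    b <- if (type == "low") c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
         else c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
    secs[[length(secs) + 1]] <- list(b = b / a[1], a = a / a[1])
  }
  if (order %% 2 == 1) {
    kk <- tan(w0 / 2)
    a <- c(1, (kk - 1) / (kk + 1))
    b <- if (type == "low") c(kk, kk) / (1 + kk) else c(1, -1) / (1 + kk)
    secs[[length(secs) + 1]] <- list(b = b, a = a)
  }
  secs
}

apply_sections <- function(secs, x) {
  for (s in secs) x <- filtfilt_zi(s$b, s$a, x)
  x
}

#' Zero-phase Butterworth bandpass
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered vector of the same length; zero phase, so peaks do not
#'   shift in time.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  check_filter_pre(x, fs, spec, spec$high_cut_hz)
  y <- apply_sections(butter_sections(spec$order, spec$low_cut_hz, fs, "high"),
                      as.numeric(x))
  apply_sections(butter_sections(spec$order, spec$high_cut_hz, fs, "low"), y)
}

#' Zero-phase powerline notch
#'
#' Second-order IIR notch (constrained biquad) at `notch_hz`, applied
#' forward-backward.
#'
#' @inheritParams bandpass_filter
#' @return Filtered vector of the same length.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  check_filter_pre(x, fs, spec, spec$notch_hz)
  w0 <- 2 * pi * spec$notch_hz / fs
  alpha <- sin(w0) / (2 * spec$notch_q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filtfilt_zi(b, a, as.numeric(x))
}

#' Apply the full cleaning chain to every channel of a record
#'
#' @param record An [ecg_record()].
#' @param spec A [filter_spec()].
#' @return The record with filtered signals (annotations untouched).
#' @export
preprocess_record <- function(record, spec = filter_spec()) {
  for (c in seq_len(nrow(record$signals))) {
    y <- bandpass_filter(record$signals[c, ], record$fs, spec)
    record$signals[c, ] <- notch_filter(y, record$fs, spec)
  }
  record
}

#' Per-channel z-score normalization of a segment
#'
#' Each channel is centred and scaled to unit standard deviation (population
#' sd); a constant channel maps to all zeros.  Amplitude varies strongly
#' between field-strength regimes, so the network always sees standardized
#' windows.
#'
#' @param segment Numeric matrix `[channels, samples]` (a vector is treated
#'   as one channel).
#' @return Matrix of the same shape.
#' @export
normalize_segment <- function(segment) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1)
  if (length(segment) == 0) stop_value("empty segment")
  mu <- rowMeans(segment)
  xc <- segment - mu
  s <- sqrt(rowMeans(xc * xc))
  s[s == 0] <- Inf
  xc / s
}
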