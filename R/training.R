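#' Training protocol settings
#'
#' Defaults follow the study protocol: Adam with a fixed learning rate of
#' 1e-3, batch size 128, 100 epochs, binary cross-entropy on the
#' sigmoid-squashed logits, and model selection by best validation DSC.
#'
#' @param epochs Number of passes over the training segments.
#' @param batch_size Segments per optimizer step.
#' @param learning_rate Adam step size.
#' @param seed Seed fixing shuffling and weight initialization.
#' @param pos_weight Optional weight on the positive (R-peak) class in the
#'   cross-entropy; 1 leaves the heavy class imbalance unweighted.
#' @param loss Loss name; only `"binary_cross_entropy"` is available.
#' @param model_selection Only `"best_val_dsc"` is available.
#' @param verbose Print one line per epoch.
#' @return Object of class `train_control`.
#' @export
train_control <- function(epochs = 100, batch_size = 128,
                          learning_rate = 1e-3, seed = 1, pos_weight = 1,
                          loss = "binary_cross_entropy",
                          model_selection = "best_val_dsc",
                          verbose = FALSE) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop_value("epochs and batch_size must be >= 1 and learning_rate > 0")
  loss <- match.arg(loss, "binary_cross_entropy")
  model_selection <- match.arg(model_selection, "best_val_dsc")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 pos_weight = pos_weight, loss = loss,
                 model_selection = model_selection,
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# Per-channel z-score of every segment in a [C, W, N] array (constant
# channels map to zeros), mirroring normalize_segment().
normalize_input_array <- function(x) {
  d <- dim(x); C <- d[1]; W <- d[2]; N <- d[3]
  xp <- matrix(aperm(x, c(2, 1, 3)), nrow = W)  # [W, C*N]
  mu <- colMeans(xp)
  xc <- xp - rep(mu, each = W)
  s <- sqrt(colMeans(xc * xc))
  s[s == 0] <- Inf
  aperm(array(xc * rep(1 / s, each = W), c(W, C, N)), c(2, 1, 3))
}

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- ptree_map2(function(m, gr) b1 * m + (1 - b1) * gr, st$m, g)
  st$v <- ptree_map2(function(v, gr) b2 * v + (1 - b2) * gr * gr, st$v, g)
  c1 <- 1 / (1 - b1^t); c2 <- 1 / (1 - b2^t)
  upd <- ptree_map2(function(m, v) (m * c1) / (sqrt(v * c2) + eps), st$m, st$v)
  p <- ptree_map2(function(pp, u) pp - lr * u, p, upd)
  list(p = p, st = st)
}

batch_logits <- function(x, config, params, chunk = 32L) {
  N <- dim(x)[3]
  out <- matrix(0, dim(x)[2], N)
  i <- 1L
  while (i <= N) {
    j <- min(i + chunk - 1L, N)
    out[, i:j] <- matrix(
      net_fwd(x[, , i:j, drop = FALSE], config, params)$logits[1, , ],
      nrow = dim(x)[2])
    i <- j + 1L
  }
  out
}

micro_dsc <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fp + fn == 0) 100 else 200 * tp / (2 * tp + fp + fn)
}

#' Fit the R-peak segmentation network
#'
#' Optimizes binary cross-entropy between the sigmoid-squashed network output
#' and the 13-sample pulse-train targets with Adam, and returns the parameter
#' snapshot from the epoch with the highest validation DSC.  Training and
#' validation sets must come from disjoint subjects; segments are per-channel
#' z-scored internally, so raw (filtered) amplitudes can be passed in.
#'
#' @param train,val [segment_set][segment_records()] objects with disjoint
#'   subjects.
#' @param config An [mhdnet_config()] or variant from [build_variant()].
#' @param control A [train_control()].
#' @return Object of class `mhdnet` with elements `params` (best epoch),
#'   `final_params`, `history` (per-epoch train loss, validation loss,
#'   validation DSC), `best_epoch`, `config`, `control` and the subject sets.
#' @export
mhdnet_fit <- function(train, val, config = mhdnet_config(),
                       control = train_control()) {
  if (!inherits(train, "segment_set") || !inherits(val, "segment_set"))
    stop_config("train and val must be segment_set objects")
  if (n_segments(train) == 0 || n_segments(val) == 0)
    stop_config("empty segment set")
  shared <- intersect(unique(train$subject_ids), unique(val$subject_ids))
  if (length(shared) > 0)
    stop_leakage(sprintf("subject(s) %s appear in both train and val",
                         paste(shared, collapse = ", ")))

  xtr <- normalize_input_array(train$inputs)
  ytr <- train$targets
  xva <- normalize_input_array(val$inputs)
  yva <- val$targets
  N <- dim(xtr)[3]
  ctl <- control

  with_seed(ctl$seed, {
    params <- mhdnet_init(config)
    zeros <- ptree_map(function(a) a * 0, unclass(params))
    st <- list(m = zeros, v = zeros)
    hist <- data.frame(epoch = seq_len(ctl$epochs), train_loss = NA_real_,
                       val_loss = NA_real_, val_dsc = NA_real_)
    best <- list(dsc = -Inf, epoch = 0L, params = params)
    tstep <- 0L
    for (ep in seq_len(ctl$epochs)) {
      ord <- sample.int(N)
      batches <- split(ord, ceiling(seq_along(ord) / ctl$batch_size))
      tot_loss <- 0
      for (bi in batches) {
        xb <- xtr[, , bi, drop = FALSE]
        yb <- ytr[, bi, drop = FALSE]
        fw <- net_fwd(xb, config, params, keep = TRUE)
        z <- matrix(fw$logits[1, , ], nrow = dim(xb)[2])
        bl <- bce_with_logits(z, yb, ctl$pos_weight)
        dlog <- array(bl$dz, c(1, dim(xb)[2], length(bi)))
        g <- net_bwd(dlog, config, params, fw$cache)
        tstep <- tstep + 1L
        up <- adam_step(unclass(params), g, st, ctl$learning_rate, tstep)
        params <- structure(up$p, class = "mhdnet_params")
        st <- up$st
        tot_loss <- tot_loss + bl$loss * length(bi)
      }
      hist$train_loss[ep] <- tot_loss / N

      zv <- batch_logits(xva, config, params)
      hist$val_loss[ep] <- bce_with_logits(zv, yva, ctl$pos_weight)$loss
      hist$val_dsc[ep] <- micro_dsc(sigmoid(zv) >= 0.5, yva >= 0.5)
      if (hist$val_dsc[ep] > best$dsc) {
        best <- list(dsc = hist$val_dsc[ep], epoch = ep, params = params)
      }
      if (ctl$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  val DSC %6.2f",
                        ep, hist$train_loss[ep], hist$val_loss[ep],
                        hist$val_dsc[ep]))
    }
    structure(
      list(params = best$params, final_params = params, config = config,
           control = ctl, history = hist, best_epoch = best$epoch,
           subjects = list(train = sort(unique(train$subject_ids)),
                           val = sort(unique(val$subject_ids))),
           fs = train$fs, window_len = train$window_len),
      class = "mhdnet")
  })
}

#' Per-sample R-peak probabilities for a whole record
#'
#' Tiles the record into non-overlapping windows of the model's input length
#' (the trailing partial window is zero-padded after standardization and the
#' prediction cropped back), normalizes each window per channel, and returns
#' the sigmoid probability of the R-peak class for every sample.
#'
#' @param record An [ecg_record()] (already preprocessed) or a numeric matrix
#'   `[in_channels, n_samples]`.
#' @param params Model parameters (`mhdnet_params`).
#' @param config The matching [mhdnet_config()].
#' @param window_len Window length in samples; defaults to 4 s at `fs` for an
#'   `ecg_record`, and must be divisible by `2^levels`.
#' @param fs Sampling rate, required when `record` is a bare matrix and
#'   `window_len` is not given.
#' @return Numeric vector of probabilities in `[0, 1]`, length `n_samples`.
#' @export
predict_masks <- function(record, params, config, window_len = NULL,
                          fs = NULL) {
  if (inherits(record, "ecg_record")) {
    fs <- record$fs
    sig <- record$signals
  } else sig <- as.matrix(record)
  if (is.null(window_len)) {
    if (is.null(fs)) stop_config("fs is required to derive the window length")
    window_len <- as.integer(round(4 * fs))
  }
  if (window_len %% 2^config$levels != 0)
    stop_shape(sprintf("window_len %d is not divisible by %d",
                       window_len, 2^config$levels))
  n <- ncol(sig)
  prob <- numeric(n)
  starts <- seq(1L, n, by = window_len)
  for (s0 in starts) {
    s1 <- min(s0 + window_len - 1L, n)
    win <- sig[, s0:s1, drop = FALSE]
    win <- normalize_segment(win)
    if (ncol(win) < window_len) {
      pad <- matrix(0, nrow(win), window_len - ncol(win))
      win <- cbind(win, pad)
    }
    z <- mhdnet_forward(win, config, params)
    prob[s0:s1] <- sigmoid(z[seq_len(s1 - s0 + 1L)])
  }
  prob
}

#' @export
print.mhdnet <- function(x, ...) {
  cat("Fitted R-peak segmentation network\n")
  print(x$config)
  cat(sprintf("  parameters: %d\n", count_params(x$params)))
  cat(sprintf("  epochs: %d (best epoch %d, validation DSC %.2f%%)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_dsc[x$best_epoch]))
  cat(sprintf("  train subjects: %s\n  val subjects:   %s\n",
              paste(x$subjects$train, collapse = ", "),
              paste(x$subjects$val, collapse = ", ")))
  invisible(x)
}

#' @export
summary.mhdnet <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.5f, val loss %.5f\n",
              h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(list(history = h, best_epoch = object$best_epoch,
                 n_params = count_params(object$params)))
}

#' @export
coef.mhdnet <- function(object, ...) object$params

#' @export
plot.mhdnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "black",
                 xlab = "epoch", ylab = "cross-entropy loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, col = "red")
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_dsc, type = "l", col = "blue", lty = 2,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("validation DSC (%)", side = 4, line = 2.5)
  graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  graphics::legend("right", legend = c("train loss", "val loss", "val DSC"),
                   col = c("black", "red", "blue"), lty = c(1, 1, 2),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Predict from a fitted segmentation network
#'
#' @param object A fitted `mhdnet` model.
#' @param newdata An [ecg_record()] or numeric matrix `[in_channels, L]`.
#' @param type `"prob"` for per-sample probabilities, `"mask"` for the
#'   thresholded binary mask, `"peaks"` for R-peak sample indices.
#' @param threshold,min_run,merge_gap_ms Peak-extraction settings, see
#'   [mask_to_peaks()].
#' @param ... Unused.
#' @return Numeric vector (probabilities or 0/1 mask) or integer peak indices.
#' @export
predict.mhdnet <- function(object, newdata, type = c("prob", "mask", "peaks"),
                           threshold = 0.5, min_run = 3, merge_gap_ms = 100,
                           ...) {
  type <- match.arg(type)
  fs <- if (inherits(newdata, "ecg_record")) newdata$fs else object$fs
  prob <- predict_masks(newdata, object$params, object$config,
                        window_len = object$window_len, fs = fs)
  switch(type,
    prob = prob,
    mask = as.integer(prob >= threshold),
    peaks = mask_to_peaks(prob, fs = fs, threshold = threshold,
                          min_run = min_run, merge_gap_ms = merge_gap_ms))
}
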