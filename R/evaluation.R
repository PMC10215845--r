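#' Extract R-peak locations from a predicted probability mask
#'
#' Binarizes at `threshold`, discards runs of positives shorter than
#' `min_run` samples, merges runs separated by less than `merge_gap_ms`, and
#' reports one peak per remaining run: the index of its maximum probability.
#' When the maximum is attained at several indices (e.g. a flat rectangular
#' run) the middle one is taken, rounding left — so a clean 13-sample label
#' pulse maps back to its central (annotated) sample.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param fs Sampling rate in Hz (converts `merge_gap_ms` to samples).
#' @param threshold Binarization threshold.
#' @param min_run Minimum run length in samples.
#' @param merge_gap_ms Runs closer than this are merged.
#' @return Sorted integer vector of 1-based peak indices (possibly empty).
#' @export
mask_to_peaks <- function(probabilities, fs, threshold = 0.5, min_run = 3,
                          merge_gap_ms = 100) {
  stopifnot(length(probabilities) > 0)
  r <- rle(probabilities >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(integer(0))
  runs <- cbind(start = starts[keep], end = ends[keep])
  gap <- as.integer(round(merge_gap_ms / 1000 * fs))
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] - 1L < gap)
        merged[nrow(merged), "end"] <- runs[i, "end"]
      else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  peaks <- integer(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    span <- merged[i, "start"]:merged[i, "end"]
    p <- probabilities[span]
    cand <- span[p == max(p)]
    peaks[i] <- cand[ceiling(length(cand) / 2)]
  }
  peaks
}

#' Match predicted against annotated peaks under a tolerance window
#'
#' Greedy one-to-one matching in order of increasing time difference: a
#' predicted peak is a true positive when it lies within
#' `floor(tolerance_ms/1000 * fs)` samples (71 samples at 1024 Hz for the
#' 70 ms rule) of an unmatched annotated peak.  Unmatched predictions are
#' false positives, unmatched annotations false negatives.
#'
#' @param predicted,truth Sorted 1-based sample indices.
#' @param fs Sampling rate in Hz.
#' @param tolerance_ms Matching tolerance in milliseconds.
#' @return Object of class `match_result`: counts `tp`, `fp`, `fn` and the
#'   `matched_pairs` matrix (columns `predicted`, `truth`).
#' @export
match_peaks <- function(predicted, truth, fs, tolerance_ms = 70) {
  if (is.unsorted(predicted) || is.unsorted(truth))
    stop_value("peak lists must be sorted")
  tol <- floor(tolerance_ms / 1000 * fs)
  np <- length(predicted); nt <- length(truth)
  cand <- NULL
  if (np > 0 && nt > 0) {
    lo <- findInterval(truth - tol - 1, predicted) + 1L
    hi <- findInterval(truth + tol, predicted)
    cand <- do.call(rbind, lapply(seq_len(nt), function(j) {
      if (lo[j] > hi[j]) return(NULL)
      i <- lo[j]:hi[j]
      cbind(i = i, j = j, d = abs(predicted[i] - truth[j]))
    }))
  }
  pairs <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("predicted", "truth")))
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[order(cand[, "d"], cand[, "j"], cand[, "i"]), , drop = FALSE]
    used_p <- logical(np); used_t <- logical(nt)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        pairs <- rbind(pairs, c(predicted[i], truth[j]))
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = nt - tp,
                 matched_pairs = pairs, tolerance_samples = tol),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP %d, FP %d, FN %d (tolerance %d samples)\n",
              x$tp, x$fp, x$fn, x$tolerance_samples))
  invisible(x)
}

#' Samplewise segmentation overlap scores
#'
#' IoU = TP/(TP+FN+FP) x 100 and DSC = 2TP/(2TP+FN+FP) x 100 over the
#' samples of predicted and true binary masks.  Two all-zero masks score 100
#' (perfect agreement on the absence of peaks).
#'
#' @param predicted_mask,truth_mask Equal-length 0/1 vectors.
#' @return List with `iou_pct` and `dsc_pct`.
#' @export
segmentation_metrics <- function(predicted_mask, truth_mask) {
  if (length(predicted_mask) != length(truth_mask))
    stop_contract("masks must have equal length")
  p <- predicted_mask > 0; t <- truth_mask > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) return(list(iou_pct = 100, dsc_pct = 100))
  list(iou_pct = 100 * tp / (tp + fn + fp),
       dsc_pct = 200 * tp / (2 * tp + fn + fp))
}

#' Detection scores from matched peak counts
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), F1 = TP/(TP + (FP+FN)/2),
#' all in percent.  Degenerate 0/0 ratios are reported as 0 with a warning.
#'
#' @param match A [match_peaks()] result (or any list with `tp`, `fp`, `fn`).
#' @return List with `recall_pct`, `precision_pct`, `f1_pct`.
#' @export
detection_metrics <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (0/0); reporting 0", what))
      0
    } else 100 * num / den
  }
  list(recall_pct = safe(tp, tp + fn, "recall"),
       precision_pct = safe(tp, tp + fp, "precision"),
       f1_pct = safe(tp, tp + (fp + fn) / 2, "F1"))
}

#' Instantaneous heart rate from consecutive R-R intervals
#'
#' @param peaks Sorted 1-based sample indices.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `length(peaks) - 1` beats-per-minute values
#'   (empty for fewer than two peaks).
#' @export
heart_rate_series <- function(peaks, fs) {
  if (length(peaks) < 2) return(numeric(0))
  60 * fs / diff(as.numeric(peaks))
}

#' Agreement between estimated and reference heart-rate series
#'
#' Pearson correlation of the paired series plus Bland-Altman statistics:
#' bias = mean(estimated - actual) and 95% limits of agreement
#' bias +/- 1.96 sd of the differences.
#'
#' @param estimated_bpm,actual_bpm Equal-length numeric vectors (>= 2 values).
#' @return Object of class `agreement_stats`: `pcc`, `bias_bpm`,
#'   `loa_low_bpm`, `loa_high_bpm`, `n`.
#' @export
agreement <- function(estimated_bpm, actual_bpm) {
  if (length(estimated_bpm) != length(actual_bpm) || length(estimated_bpm) < 2)
    stop_contract("series must have equal length >= 2")
  d <- estimated_bpm - actual_bpm
  pcc <- if (stats::sd(estimated_bpm) == 0 || stats::sd(actual_bpm) == 0) {
    warning("zero-variance series; PCC undefined")
    NA_real_
  } else stats::cor(estimated_bpm, actual_bpm)
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(pcc = pcc, bias_bpm = bias,
                 loa_low_bpm = bias - 1.96 * s,
                 loa_high_bpm = bias + 1.96 * s,
                 n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "agreement over %d pairs: PCC %.4f, bias %.3f bpm, 95%% LoA [%.3f, %.3f]\n",
    x$n, x$pcc, x$bias_bpm, x$loa_low_bpm, x$loa_high_bpm))
  invisible(x)
}

#' Paired heart-rate series from matched peaks
#'
#' For every pair of consecutive annotated peaks that are both matched by
#' predictions, computes the reference heart rate from the annotations and
#' the estimated heart rate from the corresponding predicted locations.
#'
#' @inheritParams match_peaks
#' @return List with `est_bpm`, `act_bpm` and `match` (the underlying
#'   [match_peaks()] result).
#' @export
hr_pairs <- function(predicted, truth, fs, tolerance_ms = 70) {
  m <- match_peaks(predicted, truth, fs, tolerance_ms)
  est <- numeric(0); act <- numeric(0)
  if (m$tp > 0 && length(truth) >= 2) {
    pred_of <- rep(NA_integer_, length(truth))
    pred_of[match(m$matched_pairs[, "truth"], truth)] <-
      m$matched_pairs[, "predicted"]
    for (j in seq_len(length(truth) - 1)) {
      if (!is.na(pred_of[j]) && !is.na(pred_of[j + 1]) &&
          pred_of[j + 1] > pred_of[j]) {
        act <- c(act, 60 * fs / (truth[j + 1] - truth[j]))
        est <- c(est, 60 * fs / (pred_of[j + 1] - pred_of[j]))
      }
    }
  }
  list(est_bpm = est, act_bpm = act, match = m)
}

#' Evaluate a fitted model on held-out records
#'
#' Runs the full test-time chain per record — probability mask, peak
#' extraction, tolerance matching — and micro-aggregates counts over the
#' records (samplewise for IoU/DSC, peakwise for recall/precision/F1),
#' mirroring per-fold aggregation before averaging across folds.
#'
#' @param object A fitted [mhdnet_fit()] model.
#' @param records List of (preprocessed) [ecg_record()]s.
#' @param threshold,min_run,merge_gap_ms Peak extraction, see
#'   [mask_to_peaks()].
#' @param tolerance_ms Matching tolerance.
#' @param pulse_width Label pulse width for the segmentation masks.
#' @return List with `detection`, `segmentation`, `counts`, `hr`
#'   (`agreement_stats` or `NULL` when fewer than two paired intervals) and a
#'   `per_record` data frame.
#' @export
evaluate_records <- function(object, records, threshold = 0.5, min_run = 3,
                             merge_gap_ms = 100, tolerance_ms = 70,
                             pulse_width = 13) {
  tp <- fp <- fn <- 0
  stp <- sfp <- sfn <- 0
  est <- act <- numeric(0)
  per <- list()
  for (rec in records) {
    prob <- predict_masks(rec, object$params, object$config,
                          window_len = object$window_len, fs = rec$fs)
    peaks <- mask_to_peaks(prob, fs = rec$fs, threshold = threshold,
                           min_run = min_run, merge_gap_ms = merge_gap_ms)
    hp <- hr_pairs(peaks, rec$r_peaks, rec$fs, tolerance_ms)
    m <- hp$match
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    truth_mask <- peaks_to_pulse_train(rec$r_peaks, ncol(rec$signals),
                                       pulse_width)
    pm <- prob >= threshold
    stp <- stp + sum(pm & truth_mask == 1)
    sfp <- sfp + sum(pm & truth_mask == 0)
    sfn <- sfn + sum(!pm & truth_mask == 1)
    est <- c(est, hp$est_bpm); act <- c(act, hp$act_bpm)
    per[[rec$record_id]] <- data.frame(
      record_id = rec$record_id, subject_id = rec$subject_id,
      n_truth = length(rec$r_peaks), n_predicted = length(peaks),
      tp = m$tp, fp = m$fp, fn = m$fn)
  }
  det <- detection_metrics(list(tp = tp, fp = fp, fn = fn))
  seg <- if (stp + sfp + sfn == 0) list(iou_pct = 100, dsc_pct = 100)
         else list(iou_pct = 100 * stp / (stp + sfn + sfp),
                   dsc_pct = 200 * stp / (2 * stp + sfn + sfp))
  hr <- if (length(est) >= 2) agreement(est, act) else NULL
  list(detection = det, segmentation = seg,
       counts = list(tp = tp, fp = fp, fn = fn),
       hr = hr, hr_pairs = list(est_bpm = est, act_bpm = act),
       per_record = do.call(rbind, per))
}
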