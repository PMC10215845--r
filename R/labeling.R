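#' Convert R-peak locations to a rectangular pulse-train target
#'
#' Each annotated peak becomes a rectangular pulse of height 1 and width
#' `pulse_width` samples (13 samples, about 12.7 ms at 1024 Hz), centred on
#' the peak (6 samples each side for the default width) and clipped at the
#' record boundaries.  Pulses from peaks closer than the width merge into one
#' run.
#'
#' @param peaks Sorted 1-based sample indices.
#' @param n_samples Length of the output vector.
#' @param pulse_width Pulse length in samples.
#' @return Integer 0/1 vector of length `n_samples`.
#' @export
peaks_to_pulse_train <- function(peaks, n_samples, pulse_width = 13) {
  peaks <- as.integer(peaks)
  if (length(peaks) > 0) {
    if (any(peaks < 1L) || any(peaks > n_samples))
      stop_value("peak index outside [1, n_samples]")
    if (is.unsorted(peaks, strictly = FALSE))
      stop_value("peaks must be sorted")
  }
  left <- (pulse_width - 1L) %/% 2L
  right <- pulse_width - 1L - left
  out <- integer(n_samples)
  for (p in peaks)
    out[max(1L, p - left):min(n_samples, p + right)] <- 1L
  out
}

#' Window a record into fixed-length training segments
#'
#' Cuts the record into windows of `window_s` seconds starting at multiples
#' of `stride = window_len * (1 - overlap_frac)`, pairing every window with
#' the matching slice of the record's pulse train.  75% overlap is the
#' training augmentation; use `overlap_frac = 0` for validation and test.
#'
#' @param record An [ecg_record()].
#' @param window_s Window duration in seconds.
#' @param overlap_frac Fractional overlap in `[0, 1)`.
#' @param pulse_width Label pulse width in samples.
#' @return A `segment_set`: list with `inputs` (`[channels, window_len, n]`
#'   array), `targets` (`[window_len, n]` 0/1 matrix), `subject_ids`,
#'   `window_len`, `stride` and `fs`.
#' @export
segment_record <- function(record, window_s = 4, overlap_frac = 0.75,
                           pulse_width = 13) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop_value("overlap_frac must be in [0, 1)")
  fs <- record$fs
  W <- as.integer(round(window_s * fs))
  stride <- max(1L, as.integer(round(W * (1 - overlap_frac))))
  n <- ncol(record$signals)
  C <- nrow(record$signals)
  if (n < W) {
    warning(sprintf("record '%s' (%d samples) is shorter than one window (%d)",
                    record$record_id, n, W))
    return(new_segment_set(array(0, c(C, W, 0)), matrix(0L, W, 0),
                           character(0), W, stride, fs))
  }
  starts <- seq(1L, n - W + 1L, by = stride)
  pulse <- peaks_to_pulse_train(record$r_peaks, n, pulse_width)
  inputs <- array(0, c(C, W, length(starts)))
  targets <- matrix(0L, W, length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]
    inputs[, , j] <- record$signals[, s:(s + W - 1L)]
    targets[, j] <- pulse[s:(s + W - 1L)]
  }
  new_segment_set(inputs, targets, rep(record$subject_id, length(starts)),
                  W, stride, fs)
}

new_segment_set <- function(inputs, targets, subject_ids, window_len, stride,
                            fs) {
  structure(list(inputs = inputs, targets = targets,
                 subject_ids = subject_ids,
                 window_len = as.integer(window_len),
                 stride = as.integer(stride), fs = fs),
            class = "segment_set")
}

#' Number of segments in a segment set
#' @param x A `segment_set`.
#' @return Integer count.
#' @export
n_segments <- function(x) length(x$subject_ids)

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "segment_set: %d segments of %d samples (stride %d) from %d subject(s) @ %g Hz\n",
    n_segments(x), x$window_len, x$stride,
    length(unique(x$subject_ids)), x$fs))
  invisible(x)
}

#' Window several records and pool the segments
#'
#' @param records List of [ecg_record()]s with a common sampling rate.
#' @inheritParams segment_record
#' @return A pooled `segment_set`.
#' @export
segment_records <- function(records, window_s = 4, overlap_frac = 0.75,
                            pulse_width = 13) {
  sets <- lapply(records, segment_record, window_s = window_s,
                 overlap_frac = overlap_frac, pulse_width = pulse_width)
  sets <- Filter(function(s) n_segments(s) > 0, sets)
  if (length(sets) == 0)
    stop_config("no record is long enough for a single window")
  W <- unique(vapply(sets, `[[`, integer(1), "window_len"))
  if (length(W) != 1)
    stop_config("records have inconsistent sampling rates / window lengths")
  inputs <- array(0, c(dim(sets[[1]]$inputs)[1], W,
                       sum(vapply(sets, n_segments, integer(1)))))
  targets <- matrix(0L, W, dim(inputs)[3])
  subj <- character(dim(inputs)[3])
  at <- 0L
  for (s in sets) {
    k <- n_segments(s)
    inputs[, , at + seq_len(k)] <- s$inputs
    targets[, at + seq_len(k)] <- s$targets
    subj[at + seq_len(k)] <- s$subject_ids
    at <- at + k
  }
  new_segment_set(inputs, targets, subj, W, sets[[1]]$stride, sets[[1]]$fs)
}

#' Subject-wise cross-validation folds
#'
#' Subjects are shuffled with a seeded RNG and dealt round-robin into
#' `n_folds` folds, so all records of a subject land in one fold (no leakage)
#' and fold sizes differ by at most one subject.
#'
#' @param x List of [ecg_record()]s, or a character vector of subject ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed making the assignment deterministic.
#' @return A `fold_split`: list with `n_folds` and `assignment` (named
#'   integer vector, subject -> fold).
#' @export
subject_folds <- function(x, n_folds = 5, seed = 1) {
  subjects <- if (is.character(x)) unique(x)
              else unique(vapply(x, `[[`, character(1), "subject_id"))
  if (length(subjects) < n_folds)
    stop_config(sprintf("%d subjects cannot fill %d folds",
                        length(subjects), n_folds))
  shuffled <- with_seed(seed, sample(subjects))
  assignment <- ((seq_along(shuffled) - 1L) %% n_folds) + 1L
  names(assignment) <- shuffled
  structure(list(n_folds = as.integer(n_folds),
                 assignment = assignment[order(names(assignment))]),
            class = "fold_split")
}

#' Train/validation/test subject sets for one cross-validation round
#'
#' Round `test_fold` uses that fold as the test set, the next fold
#' (cyclically) as validation, and the remaining `n_folds - 2` folds for
#' training.
#'
#' @param split A [subject_folds()] result.
#' @param test_fold Which fold (1..n_folds) plays the test role.
#' @return List of character vectors `train`, `val`, `test`.
#' @export
fold_rotation <- function(split, test_fold) {
  n <- split$n_folds
  if (test_fold < 1 || test_fold > n) stop_value("test_fold out of range")
  val_fold <- (test_fold %% n) + 1L
  a <- split$assignment
  list(train = names(a)[!a %in% c(test_fold, val_fold)],
       val = names(a)[a == val_fold],
       test = names(a)[a == test_fold])
}

#' Write / read a fold assignment as CSV
#'
#' @param split A `fold_split`.
#' @param path CSV path (columns `subject`, `fold`).
#' @return `write_folds` the path invisibly; `read_folds` a `fold_split`.
#' @export
write_folds <- function(split, path) {
  utils::write.csv(data.frame(subject = names(split$assignment),
                              fold = as.integer(split$assignment)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  a <- as.integer(df$fold)
  names(a) <- df$subject
  structure(list(n_folds = max(a), assignment = a[order(names(a))]),
            class = "fold_split")
}
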