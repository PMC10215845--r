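# YAML-driven experiment runs: one config file per experiment (3T-like and
# 7T-like artifact regimes are separate configs and separately trained
# models).  A single `seed` fixes the generator, the fold assignment and
# training.

run_config_schema <- function() {
  list(
    seed = 1L,
    out_dir = "runs/run1",
    data = list(root = NULL, field_strength = "synthetic",
                manifest = "manifest.csv"),
    synthetic = list(n_subjects = 5L, records_per_subject = 2L,
                     duration_s = 60, fs = 1024, hr_mean_bpm = 70,
                     hr_sd_bpm = 5, rr_jitter_frac = 0.05,
                     preset = "7T", mhd_severity = NULL,
                     baseline_wander_amp = 0.15, noise_sd = 0.05,
                     powerline_amp_50hz = 0.05),
    filter = list(low_cut_hz = 0.05, high_cut_hz = 100, notch_hz = 50,
                  notch_q = 30, order = 4L),
    windowing = list(window_s = 4, train_overlap = 0.75, pulse_width = 13L),
    model = list(variant = "self_attention_mhdnet", levels = 4L,
                 base_filters = 16L, kernel_size = 11L, q = 3L),
    training = list(epochs = 100L, batch_size = 128L, learning_rate = 1e-3,
                    pos_weight = 1, verbose = FALSE),
    evaluation = list(threshold = 0.5, min_run = 3L, merge_gap_ms = 100,
                      tolerance_ms = 70),
    folds = list(n_folds = 5L, test_fold = 1L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop_config(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop_config(sprintf("'%s' must be a mapping", full))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else defaults[key] <- user[key]
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with an error naming the offending key; absent
#' keys take package defaults.  Sections: `data` (dataset root and field
#' strength), `synthetic` (generator), `filter`, `windowing`, `model`
#' (variant name and size), `training`, `evaluation`, `folds`, plus a global
#' `seed` and `out_dir`.
#'
#' @param path YAML file path.
#' @return Object of class `run_config` (nested list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: '%s'", path))
  user <- yaml::read_yaml(path)
  cfg <- merge_config(run_config_schema(), user %||% list())
  if (is.null(cfg$data$root))
    cfg$data$root <- file.path(cfg$out_dir, "data")
  structure(cfg, class = "run_config")
}

config_to_synth <- function(cfg) {
  s <- cfg$synthetic
  sev <- s$mhd_severity %||% (if (identical(s$preset, "3T")) 0.5 else 1)
  synth_config(n_subjects = s$n_subjects,
               records_per_subject = s$records_per_subject,
               duration_s = s$duration_s, fs = s$fs,
               hr_mean_bpm = s$hr_mean_bpm, hr_sd_bpm = s$hr_sd_bpm,
               rr_jitter_frac = s$rr_jitter_frac, mhd_severity = sev,
               baseline_wander_amp = s$baseline_wander_amp,
               noise_sd = s$noise_sd,
               powerline_amp_50hz = s$powerline_amp_50hz,
               seed = cfg$seed)
}

config_to_model <- function(cfg) {
  m <- cfg$model
  build_variant(m$variant, levels = m$levels, base_filters = m$base_filters,
                kernel_size = m$kernel_size, q = m$q)
}

config_to_filter <- function(cfg) {
  f <- cfg$filter
  filter_spec(f$low_cut_hz, f$high_cut_hz, f$notch_hz, f$notch_q, f$order)
}

load_and_preprocess <- function(cfg) {
  recs <- load_dataset(cfg$data$root, cfg$data$field_strength,
                       manifest = cfg$data$manifest)
  lapply(recs, preprocess_record, spec = config_to_filter(cfg))
}

#' Pipeline commands driven by a run configuration
#'
#' * `run_simulate()` writes a synthetic WFDB dataset to `data.root`.
#' * `run_preprocess()` writes filtered copies of the dataset under
#'   `out_dir/preprocessed`.
#' * `run_train()` builds subject-wise folds, trains on the 3 training folds
#'   of rotation `folds.test_fold` with the 4th as validation, and writes
#'   `checkpoint.rds`, `history.csv` and `folds.csv` under `out_dir`.
#' * `run_evaluate()` scores the checkpoint on the held-out test fold and
#'   writes `metrics.csv` (+ `metrics.yaml`).
#' * `run_crossval()` rotates the train/val/test assignment over all folds,
#'   training one model per rotation, and writes per-fold and mean metrics.
#'
#' All commands are deterministic given the same config and seed.
#'
#' @param cfg A [read_run_config()] object.
#' @return `run_simulate` the manifest path; `run_train` the fitted model
#'   (invisibly); `run_evaluate` the metrics list; `run_crossval` a list with
#'   per-fold and mean metrics.
#' @name run_commands
NULL

#' @rdname run_commands
#' @export
run_simulate <- function(cfg) {
  make_synthetic_dataset(config_to_synth(cfg), cfg$data$root)
}

#' @rdname run_commands
#' @export
run_preprocess <- function(cfg) {
  recs <- load_and_preprocess(cfg)
  out <- file.path(cfg$out_dir, "preprocessed")
  for (r in recs) write_record(r, out)
  file.copy(file.path(cfg$data$root, cfg$data$manifest),
            file.path(out, cfg$data$manifest), overwrite = TRUE)
  invisible(out)
}

fit_fold <- function(cfg, recs, split, test_fold) {
  rot <- fold_rotation(split, test_fold)
  subj <- vapply(recs, `[[`, character(1), "subject_id")
  w <- cfg$windowing
  train <- segment_records(recs[subj %in% rot$train], window_s = w$window_s,
                           overlap_frac = w$train_overlap,
                           pulse_width = w$pulse_width)
  val <- segment_records(recs[subj %in% rot$val], window_s = w$window_s,
                         overlap_frac = 0, pulse_width = w$pulse_width)
  ctl <- train_control(epochs = cfg$training$epochs,
                       batch_size = cfg$training$batch_size,
                       learning_rate = cfg$training$learning_rate,
                       seed = cfg$seed, pos_weight = cfg$training$pos_weight,
                       verbose = cfg$training$verbose)
  fit <- mhdnet_fit(train, val, config_to_model(cfg), ctl)
  list(fit = fit, rot = rot)
}

eval_fold <- function(cfg, recs, rot, fit) {
  subj <- vapply(recs, `[[`, character(1), "subject_id")
  ev <- cfg$evaluation
  evaluate_records(fit, recs[subj %in% rot$test], threshold = ev$threshold,
                   min_run = ev$min_run, merge_gap_ms = ev$merge_gap_ms,
                   tolerance_ms = ev$tolerance_ms,
                   pulse_width = cfg$windowing$pulse_width)
}

#' @rdname run_commands
#' @export
run_train <- function(cfg) {
  recs <- load_and_preprocess(cfg)
  split <- subject_folds(recs, n_folds = cfg$folds$n_folds, seed = cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ff <- fit_fold(cfg, recs, split, cfg$folds$test_fold)
  save_checkpoint(ff$fit, file.path(cfg$out_dir, "checkpoint.rds"))
  utils::write.csv(ff$fit$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  write_folds(split, file.path(cfg$out_dir, "folds.csv"))
  invisible(ff$fit)
}

#' @rdname run_commands
#' @export
run_evaluate <- function(cfg) {
  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  if (!file.exists(ckpt))
    stop_io(sprintf("checkpoint not found: '%s' (run train first)", ckpt))
  fit <- load_checkpoint(ckpt)
  recs <- load_and_preprocess(cfg)
  split <- subject_folds(recs, n_folds = cfg$folds$n_folds, seed = cfg$seed)
  rot <- fold_rotation(split, cfg$folds$test_fold)
  res <- eval_fold(cfg, recs, rot, fit)
  df <- data.frame(fold = cfg$folds$test_fold,
                   recall_pct = res$detection$recall_pct,
                   precision_pct = res$detection$precision_pct,
                   f1_pct = res$detection$f1_pct,
                   iou_pct = res$segmentation$iou_pct,
                   dsc_pct = res$segmentation$dsc_pct)
  utils::write.csv(df, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(detection = res$detection,
                        segmentation = res$segmentation,
                        counts = res$counts),
                   file.path(cfg$out_dir, "metrics.yaml"))
  res
}

#' @rdname run_commands
#' @export
run_crossval <- function(cfg) {
  recs <- load_and_preprocess(cfg)
  split <- subject_folds(recs, n_folds = cfg$folds$n_folds, seed = cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (f in seq_len(cfg$folds$n_folds)) {
    ff <- fit_fold(cfg, recs, split, f)
    res <- eval_fold(cfg, recs, ff$rot, ff$fit)
    rows[[f]] <- data.frame(fold = f,
                            recall_pct = res$detection$recall_pct,
                            precision_pct = res$detection$precision_pct,
                            f1_pct = res$detection$f1_pct,
                            iou_pct = res$segmentation$iou_pct,
                            dsc_pct = res$segmentation$dsc_pct)
  }
  per_fold <- do.call(rbind, rows)
  mean_row <- colMeans(per_fold[, -1])
  utils::write.csv(per_fold, file.path(cfg$out_dir, "metrics_per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(t(mean_row)),
                   file.path(cfg$out_dir, "metrics_mean.csv"),
                   row.names = FALSE)
  list(per_fold = per_fold, mean = mean_row)
}

#' Save / load a fitted model checkpoint
#'
#' One-file archive holding the architecture configuration (embedded as a
#' YAML text block) together with all parameter arrays and the training
#' history; reload is bit-exact.
#'
#' @param fit A fitted `mhdnet` object.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the
#'   restored `mhdnet` object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mhdnet"))
  saveRDS(list(format = "mhdnet-checkpoint-1",
               config_yaml = yaml::as.yaml(unclass(fit$config)),
               fit = fit),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("checkpoint not found: '%s'", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "mhdnet-checkpoint-1"))
    stop_format(sprintf("'%s' is not an mhdnet checkpoint", path))
  obj$fit
}
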