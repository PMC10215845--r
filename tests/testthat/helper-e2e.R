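# Scaled-down end-to-end study: 5 subjects x 2 x 60 s synthetic records with
# the severe ("7T-like") artifact, one subject-wise train/val/test split, a
# reduced model (2 levels, 8 base filters, kernel 11, q = 3) trained for 15
# epochs at batch 32.  Shared (memoized) across the acceptance tests because
# it is by far the most expensive computation in the suite.

.e2e_cache <- new.env(parent = emptyenv())

scaled_e2e <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  gen <- synth_preset("7T", n_subjects = 5, records_per_subject = 2,
                      duration_s = 60, fs = 1024, seed = seed)
  dir <- tempfile("e2e7t")
  make_synthetic_dataset(gen, dir)
  recs <- lapply(load_dataset(dir, "synthetic"), preprocess_record)
  unlink(dir, recursive = TRUE)
  split <- subject_folds(recs, n_folds = 5, seed = seed)
  rot <- fold_rotation(split, 1)
  subj <- vapply(recs, `[[`, character(1), "subject_id")
  train <- segment_records(recs[subj %in% rot$train], overlap_frac = 0.75)
  val <- segment_records(recs[subj %in% rot$val], overlap_frac = 0)
  test_recs <- recs[subj %in% rot$test]
  ctl <- train_control(epochs = 15, batch_size = 32, seed = seed)
  out <- list(seed = seed, rot = rot, n_test_peaks = sum(
    vapply(test_recs, function(r) length(r$r_peaks), integer(1))))
  for (v in c("self_attention_mhdnet", "fpn_cnn")) {
    cfg <- build_variant(v, levels = 2, base_filters = 8)
    fit <- mhdnet_fit(train, val, cfg, ctl)
    out[[v]] <- evaluate_records(fit, test_recs)
  }
  .e2e_cache[[key]] <- out
  out
}
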