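# Shared fixtures, built in code at test time.

# Amplitude of the f-Hz component of a signal, by projection onto the
# quadrature pair over a window — isolates the component the
# frequency-response oracle predicts, independent of slow edge transients.
component_amp <- function(x, f, fs, window = seq_along(x)) {
  tt <- (window - 1) / fs
  xs <- x[window]
  sqrt(mean(xs * sin(2 * pi * f * tt))^2 +
       mean(xs * cos(2 * pi * f * tt))^2) * 2
}

# |H| of a cascade of biquad sections at frequency f.
sections_gain <- function(secs, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  prod(vapply(secs, function(s) {
    abs(sum(s$b * z^(seq_along(s$b) - 1)) /
        sum(s$a * z^(seq_along(s$a) - 1)))
  }, numeric(1)))
}

# A small synthetic record; fs = 256 keeps windows at 1024 samples so the
# network trains in seconds.
tiny_record <- function(duration_s = 12, fs = 256, severity = 0, seed = 3,
                        subject = "s1", record = "s1_r01") {
  cfg <- synth_config(n_subjects = 1, records_per_subject = 1,
                      duration_s = duration_s, fs = fs, hr_sd_bpm = 0,
                      mhd_severity = severity, seed = seed)
  make_synthetic_record(cfg, subject, record)
}

# Memoized small trained model shared by the training tests.
.fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache$fit)
  recs <- lapply(1:3, function(i)
    tiny_record(duration_s = 12, fs = 256, severity = 0.5, seed = 20 + i,
                subject = sprintf("s%d", i),
                record = sprintf("s%d_r01", i)))
  train <- segment_records(recs[1:2], overlap_frac = 0.75)
  val <- segment_records(recs[3], overlap_frac = 0)
  cfg <- build_variant("self_attention_mhdnet", levels = 2, base_filters = 4)
  ctl <- train_control(epochs = 6, batch_size = 16, seed = 5)
  .fit_cache$fit <- mhdnet_fit(train, val, cfg, ctl)
  .fit_cache$records <- recs
  .fit_cache$fit
}
tiny_fit_records <- function() {
  tiny_fit()
  .fit_cache$records
}
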