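# Training protocol: convergence, determinism, leakage guards, model
# selection and whole-record prediction.  Small models at 256 Hz keep each
# fit to a few seconds.

test_that("a memorizable batch is overfit to near-perfect training DSC", {
  rec <- tiny_record(duration_s = 12, fs = 256, severity = 0.5, seed = 7)
  train <- segment_record(rec, overlap_frac = 0.5)
  # separate subject for validation so the fit is legal
  val <- segment_record(tiny_record(duration_s = 8, fs = 256, severity = 0.5,
                                    seed = 8, subject = "s2"),
                        overlap_frac = 0)
  cfg <- mhdnet_config(levels = 2, base_filters = 8)
  ctl <- train_control(epochs = 200, batch_size = n_segments(train),
                       seed = 2)
  fit <- mhdnet_fit(train, val, cfg, ctl)
  xt <- mhdnet:::normalize_input_array(train$inputs)
  z <- mhdnet:::batch_logits(xt, cfg, fit$final_params)
  dsc <- mhdnet:::micro_dsc(mhdnet:::sigmoid(z) >= 0.5, train$targets >= 0.5)
  expect_gte(dsc, 99)
})

test_that("training is deterministic under a fixed seed", {
  recs <- tiny_fit_records()
  train <- segment_records(recs[1:2], overlap_frac = 0.5)
  val <- segment_records(recs[3], overlap_frac = 0)
  cfg <- mhdnet_config(levels = 2, base_filters = 2)
  ctl <- train_control(epochs = 2, batch_size = 16, seed = 9)
  f1 <- mhdnet_fit(train, val, cfg, ctl)
  f2 <- mhdnet_fit(train, val, cfg, ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("subject leakage and empty inputs are rejected", {
  recs <- tiny_fit_records()
  train <- segment_records(recs[1:2], overlap_frac = 0.5)
  same <- segment_records(recs[2], overlap_frac = 0)
  cfg <- mhdnet_config(levels = 2, base_filters = 2)
  expect_error(mhdnet_fit(train, same, cfg, train_control(epochs = 1)),
               class = "mhdnet_leakage_error")
  expect_error(mhdnet_fit(train, list(), cfg), class = "mhdnet_config_error")
})

test_that("loss decreases and model selection tracks best validation DSC", {
  fit <- tiny_fit()
  h <- fit$history
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_equal(fit$best_epoch, which.max(h$val_dsc))
  expect_equal(h$val_dsc[fit$best_epoch], max(h$val_dsc))
})

test_that("a trained model separates in-pulse from out-of-pulse samples", {
  fit <- tiny_fit()
  rec <- tiny_fit_records()[[3]]
  prob <- predict(fit, rec, type = "prob")
  expect_length(prob, ncol(rec$signals))
  expect_true(all(prob >= 0 & prob <= 1))
  pulse <- peaks_to_pulse_train(rec$r_peaks, ncol(rec$signals))
  expect_gt(mean(prob[pulse == 1]), mean(prob[pulse == 0]))
})

test_that("prediction crops zero-padded trailing windows to record length", {
  fit <- tiny_fit()
  sig <- matrix(rnorm(3 * 2500), 3, 2500)   # 2.44 windows at 1024 samples
  prob <- predict_masks(sig, fit$params, fit$config, window_len = 1024)
  expect_length(prob, 2500)
  expect_true(all(prob >= 0 & prob <= 1))
  short <- matrix(rnorm(3 * 700), 3, 700)   # shorter than one window
  expect_length(predict_masks(short, fit$params, fit$config,
                              window_len = 1024), 700)
})

test_that("untrained parameters still emit valid probabilities", {
  cfg <- mhdnet_config(levels = 2, base_filters = 2)
  par <- mhdnet_init(cfg, seed = 3)
  prob <- predict_masks(matrix(rnorm(3 * 1024), 3, 1024), par, cfg,
                        window_len = 1024)
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("fit object methods report coherently", {
  fit <- tiny_fit()
  expect_output(print(fit), "Fitted R-peak segmentation network")
  expect_identical(coef(fit), fit$params)
  s <- summary(fit)
  expect_equal(s$n_params, count_params(fit$params))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.size(path) > 0)
})

test_that("checkpoints reload bit-exactly", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, fit$params)
  expect_identical(unclass(back$config), unclass(fit$config))
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds")),
               class = "mhdnet_io_error")
})
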