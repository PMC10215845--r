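# Peak extraction, tolerance matching, segmentation/detection scores and
# heart-rate agreement.

test_that("mask_to_peaks recovers pulse-train centres and drops short runs", {
  pt <- peaks_to_pulse_train(c(100, 500), 1000, 13)
  expect_identical(mask_to_peaks(pt, fs = 1024), c(100L, 500L))
  expect_identical(mask_to_peaks(numeric(500), fs = 1024), integer(0))
  two <- numeric(400); two[c(100, 101, 300, 301)] <- 1  # runs of length 2
  expect_identical(mask_to_peaks(two, fs = 1024, min_run = 3), integer(0))
})

test_that("runs closer than the merge gap collapse into one detection", {
  p <- numeric(1000)
  p[100:105] <- 0.8
  p[140:146] <- 0.9  # 34-sample gap < 100 ms at 1024 Hz
  expect_identical(mask_to_peaks(p, fs = 1024), 143L)  # argmax of merged run
  p2 <- numeric(1000)
  p2[100:105] <- 0.8
  p2[400:406] <- 0.9
  expect_length(mask_to_peaks(p2, fs = 1024), 2)
})

test_that("the 70 ms rule admits 48.8 ms and rejects 97.7 ms offsets", {
  m_in <- match_peaks(1050, 1000, fs = 1024)
  expect_equal(m_in$tolerance_samples, 71)
  expect_equal(c(m_in$tp, m_in$fp, m_in$fn), c(1, 0, 0))
  m_out <- match_peaks(1100, 1000, fs = 1024)
  expect_equal(c(m_out$tp, m_out$fp, m_out$fn), c(0, 1, 1))
  m_none <- match_peaks(integer(0), 1000, fs = 1024)
  expect_equal(c(m_none$tp, m_none$fp, m_none$fn), c(0, 0, 1))
  expect_error(match_peaks(c(5, 3), 10, fs = 1024),
               class = "mhdnet_value_error")
})

test_that("matching is one-to-one and greedy by time difference", {
  # two predictions near one truth: only the closer one matches
  m <- match_peaks(c(990, 1010), 1000, fs = 1024)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
  # 990 and 1010 are equidistant; the earlier prediction wins the tie
  expect_equal(unname(m$matched_pairs[1, "predicted"]), 990)
  m2 <- match_peaks(c(995, 1010), 1000, fs = 1024)
  expect_equal(unname(m2$matched_pairs[1, "predicted"]), 995)
})

test_that("matching invariants hold on random peak sets", {
  set.seed(21)
  for (i in 1:40) {
    truth <- sort(sample(1:50000, sample(5:40, 1)))
    pred <- sort(sample(1:50000, sample(0:40, 1)))
    m <- match_peaks(pred, truth, fs = 1024)
    expect_lte(m$tp, min(length(pred), length(truth)))
    expect_equal(m$tp + m$fn, length(truth))
    expect_equal(m$tp + m$fp, length(pred))
    if (m$tp > 0)
      expect_true(all(abs(m$matched_pairs[, 1] - m$matched_pairs[, 2]) <= 71))
  }
})

test_that("segmentation worked examples score exactly", {
  a <- integer(100); a[10:30] <- 1L
  expect_equal(segmentation_metrics(a, a), list(iou_pct = 100, dsc_pct = 100))
  p <- integer(100); p[1:10] <- 1L
  t <- integer(100); t[6:15] <- 1L
  sm <- segmentation_metrics(p, t)   # TP 5, FP 5, FN 5
  expect_equal(sm$iou_pct, 100 / 3, tolerance = 1e-12)
  expect_equal(sm$dsc_pct, 50)
  expect_equal(segmentation_metrics(integer(100), t),
               list(iou_pct = 0, dsc_pct = 0))
  expect_equal(segmentation_metrics(integer(10), integer(10)),
               list(iou_pct = 100, dsc_pct = 100))
  expect_error(segmentation_metrics(1:3, 1:4), class = "mhdnet_contract_error")
})

test_that("IoU never exceeds DSC", {
  set.seed(22)
  for (i in 1:50) {
    p <- rbinom(200, 1, runif(1, 0.05, 0.5))
    t <- rbinom(200, 1, runif(1, 0.05, 0.5))
    sm <- segmentation_metrics(p, t)
    expect_lte(sm$iou_pct, sm$dsc_pct + 1e-12)
  }
})

test_that("detection metrics follow the counting formulas", {
  d <- detection_metrics(list(tp = 99, fp = 1, fn = 1))
  expect_equal(c(d$recall_pct, d$precision_pct, d$f1_pct), c(99, 99, 99))
  d2 <- detection_metrics(list(tp = 3, fp = 1, fn = 0))
  expect_equal(d2$recall_pct, 100)
  expect_equal(d2$precision_pct, 75)
  expect_equal(d2$f1_pct, 100 * 3 / 3.5, tolerance = 1e-9)
  w <- capture_warnings(d0 <- detection_metrics(list(tp = 0, fp = 0, fn = 0)))
  expect_length(w, 3)  # recall, precision and F1 each warn on 0/0
  expect_equal(c(d0$recall_pct, d0$precision_pct, d0$f1_pct), c(0, 0, 0))
})

test_that("heart-rate series converts R-R intervals to bpm", {
  expect_equal(heart_rate_series(seq(1, by = 768, length.out = 10), 1024),
               rep(80, 9))
  expect_equal(heart_rate_series(c(1, 1025), 1024), 60)
  expect_equal(heart_rate_series(500, 1024), numeric(0))
})

test_that("agreement reproduces hand-computed Bland-Altman statistics", {
  a <- agreement(c(60, 70, 80) + 2, c(60, 70, 80))
  expect_equal(a$pcc, 1)
  expect_equal(a$bias_bpm, 2)
  expect_equal(c(a$loa_low_bpm, a$loa_high_bpm), c(2, 2))
  # est (60,70,80) vs act (60,72,78): diffs (0,-2,2) -> bias 0, sd 2,
  # LoA -/+ 3.92; pcc = 90 / (10 * sqrt(84))
  h <- agreement(c(60, 70, 80), c(60, 72, 78))
  expect_equal(h$bias_bpm, 0)
  expect_equal(h$loa_low_bpm, -3.92)
  expect_equal(h$loa_high_bpm, 3.92)
  expect_equal(h$pcc, 90 / (10 * sqrt(84)), tolerance = 1e-12)
  expect_warning(z <- agreement(rep(60, 5), 1:5 * 10))
  expect_true(is.na(z$pcc))
  expect_error(agreement(1:3, 1:4), class = "mhdnet_contract_error")
})

test_that("hr_pairs pairs consecutive matched intervals only", {
  fs <- 1024
  truth <- c(1000, 1800, 2600, 3400)
  pred <- c(1010, 1790, 3390)         # third truth peak missed
  hp <- hr_pairs(pred, truth, fs)
  # only the (1000, 1800) interval has both ends matched
  expect_equal(hp$act_bpm, 60 * fs / 800)
  expect_equal(hp$est_bpm, 60 * fs / (1790 - 1010))
})
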