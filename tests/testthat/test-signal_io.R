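# WFDB-compatible reader/writer and the manifest-driven dataset loader.

make_rec <- function(n = 4096, peaks = c(1001, 2001), channels = 3,
                     names = c("I", "II", "III"), fs = 1024, id = "rec01") {
  set.seed(1)
  ecg_record(id, "subjA", "synthetic", fs,
             matrix(rnorm(channels * n), channels, n), names, peaks)
}

test_that("write + read round-trips annotations, names and signals", {
  d <- withr::local_tempdir()
  rec <- make_rec()
  write_record(rec, d, gain = 2000)
  back <- read_record(file.path(d, "rec01.hea"), file.path(d, "rec01.atr"))
  expect_identical(back$r_peaks, rec$r_peaks)
  expect_identical(back$channel_names, rec$channel_names)
  expect_equal(back$fs, rec$fs)
  expect_equal(ncol(back$signals), 4096)
  expect_lt(max(abs(back$signals - rec$signals)), 1 / (2 * 2000) + 1e-9)
})

test_that("long inter-annotation gaps survive the round trip", {
  d <- withr::local_tempdir()
  rec <- make_rec(n = 60000, peaks = c(5L, 1100L, 59999L))
  write_record(rec, d)
  back <- read_record(file.path(d, "rec01.hea"), file.path(d, "rec01.atr"))
  expect_identical(back$r_peaks, c(5L, 1100L, 59999L))
})

test_that("leads I, II, III are selected by name from a 12-lead record", {
  d <- withr::local_tempdir()
  nm <- c("I", "II", "III", "AVR", "AVL", "AVF",
          "V1", "V2", "V3", "V4", "V5", "V6")
  rec <- make_rec(channels = 12, names = nm, id = "rec12")
  write_record(rec, d)
  back <- read_record(file.path(d, "rec12.hea"), file.path(d, "rec12.atr"))
  expect_identical(back$channel_names, c("I", "II", "III"))
  expect_equal(nrow(back$signals), 3)
  expect_lt(max(abs(back$signals - rec$signals[1:3, ])), 1e-3)
})

test_that("unnamed channels fall back to the first three with a warning", {
  d <- withr::local_tempdir()
  rec <- make_rec(names = c("chan a", "chan b", "chan c"), id = "recx")
  write_record(rec, d)
  expect_warning(
    back <- read_record(file.path(d, "recx.hea"), file.path(d, "recx.atr")),
    "first three")
  expect_equal(nrow(back$signals), 3)
})

test_that("missing files and empty annotation streams raise typed errors", {
  d <- withr::local_tempdir()
  rec <- make_rec()
  write_record(rec, d)
  expect_error(read_record(file.path(d, "nope.hea"), file.path(d, "rec01.atr")),
               class = "mhdnet_io_error")
  expect_error(read_record(file.path(d, "rec01.hea"), file.path(d, "nope.atr")),
               class = "mhdnet_annotation_error")
  empty <- make_rec(peaks = integer(0), id = "rec00")
  paths <- write_record(empty, d)
  expect_true(file.exists(paths$ann))
  expect_equal(file.size(paths$ann), 2)  # just the terminating word
  expect_error(read_record(file.path(d, "rec00.hea"), paths$ann),
               class = "mhdnet_annotation_error")
})

test_that("header states sampling rate and channel count", {
  d <- withr::local_tempdir()
  write_record(make_rec(), d)
  top <- strsplit(readLines(file.path(d, "rec01.hea"))[1], " ")[[1]]
  expect_equal(as.integer(top[2]), 3)
  expect_equal(as.numeric(top[3]), 1024)
  expect_equal(as.integer(top[4]), 4096)
})

test_that("record validation enforces the peak invariants", {
  expect_error(make_rec(peaks = c(2001, 1001)), class = "mhdnet_value_error")
  expect_error(make_rec(peaks = c(1, 5000)), class = "mhdnet_value_error")
  expect_error(ecg_record("r", "s", "9T", 1024, matrix(0, 3, 10),
                          c("I", "II", "III"), integer(0)),
               class = "mhdnet_value_error")
})

test_that("load_dataset groups by subject and filters by field strength", {
  d <- withr::local_tempdir()
  for (s in c("a", "b")) for (r in 1:2) {
    rec <- make_rec(id = sprintf("%s_r%d", s, r))
    rec$subject_id <- s
    write_record(rec, d)
  }
  mf <- data.frame(record = c("a_r1", "a_r2", "b_r1", "b_r2"),
                   subject = c("a", "a", "b", "b"),
                   field_strength = "synthetic")
  write.csv(mf, file.path(d, "manifest.csv"), row.names = FALSE)
  recs <- load_dataset(d, "synthetic")
  expect_length(recs, 4)
  expect_setequal(vapply(recs, `[[`, character(1), "subject_id"), c("a", "b"))
  expect_identical(vapply(recs, `[[`, character(1), "record_id"),
                   sort(mf$record))
  expect_error(load_dataset(d, "7T"), class = "mhdnet_config_error")
  expect_error(load_dataset(file.path(d, "missing"), "synthetic"),
               class = "mhdnet_io_error")
})

test_that("a generator-written tree loads with the generator's truth", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_subjects = 2, records_per_subject = 1,
                      duration_s = 6, fs = 256, seed = 9)
  mpath <- make_synthetic_dataset(cfg, d)
  truth <- attr(mpath, "r_peaks")
  recs <- load_dataset(d, "synthetic")
  expect_length(recs, 2)
  for (r in recs) {
    expect_gt(length(r$r_peaks), 3)
    expect_identical(r$r_peaks, truth[[r$record_id]])
  }
  # determinism: the same config writes byte-identical signal files
  d2 <- withr::local_tempdir()
  make_synthetic_dataset(cfg, d2)
  f1 <- list.files(d, "\\.dat$", full.names = TRUE)
  f2 <- list.files(d2, "\\.dat$", full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
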