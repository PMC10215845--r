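#' Multichannel ECG record with R-peak annotations
#'
#' Container for one subject's ECG: a `[n_channels, n_samples]` signal matrix
#' at a fixed sampling rate, the annotated R-peak locations, and provenance
#' (subject and static-field strength).  Peak locations are 1-based sample
#' indices; time in seconds is `(index - 1) / fs`.
#'
#' @param record_id,subject_id Identifiers; all records of one subject share
#'   `subject_id` so cross-validation can split without leakage.
#' @param field_strength One of `"3T"`, `"7T"`, `"synthetic"`.
#' @param fs Sampling rate in Hz (the source data use 1024).
#' @param signals Numeric matrix `[n_channels, n_samples]`.
#' @param channel_names Lead labels, one per row of `signals`.
#' @param r_peaks Strictly increasing 1-based sample indices of the R-peaks.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, subject_id, field_strength, fs, signals,
                       channel_names, r_peaks) {
  rec <- structure(
    list(record_id = as.character(record_id),
         subject_id = as.character(subject_id),
         field_strength = as.character(field_strength),
         fs = as.numeric(fs),
         signals = as.matrix(signals),
         channel_names = as.character(channel_names),
         r_peaks = as.integer(r_peaks)),
    class = "ecg_record")
  validate_ecg_record(rec)
}

validate_ecg_record <- function(rec) {
  if (!rec$field_strength %in% c("3T", "7T", "synthetic"))
    stop_value(sprintf("unknown field_strength '%s'", rec$field_strength))
  if (rec$fs <= 0) stop_value("fs must be positive")
  if (nrow(rec$signals) != length(rec$channel_names))
    stop_value("channel_names must match the signal rows")
  if (any(!is.finite(rec$signals)))
    stop_format("signals contain non-finite values")
  n <- ncol(rec$signals)
  if (length(rec$r_peaks) > 0) {
    if (any(rec$r_peaks < 1L) || any(rec$r_peaks > n))
      stop_value("r_peaks outside [1, n_samples]")
    if (any(diff(rec$r_peaks) <= 0L))
      stop_value("r_peaks must be strictly increasing")
  }
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "ecg_record '%s' (subject %s, %s): %d channels [%s] x %d samples @ %g Hz, %d R-peaks\n",
    x$record_id, x$subject_id, x$field_strength, nrow(x$signals),
    paste(x$channel_names, collapse = ", "), ncol(x$signals), x$fs,
    length(x$r_peaks)))
  invisible(x)
}

# MIT annotation codes conventionally used for beat labels.
mit_beat_codes <- function() c(1:13, 25L, 34L, 35L, 38L)

# ---- MIT-format annotation stream ------------------------------------------
# Two-byte little-endian words: top 6 bits = annotation code, low 10 bits =
# sample interval since the previous annotation.  Intervals above 1023 are
# carried by a SKIP word (code 59) followed by a 4-byte interval (high word
# first); the stream ends with a zero word.

write_annotations <- function(path, peaks, code = 1L) {
  words <- integer(0)
  prev <- 0
  for (p in peaks) {
    delta <- (p - 1L) - prev                    # file format is 0-based
    if (delta > 1023) {
      words <- c(words, bitwShiftL(59L, 10L),
                 delta %/% 65536L, delta %% 65536L)
      delta <- 0L
    }
    words <- c(words, bitwShiftL(code, 10L) + delta)
    prev <- p - 1L
  }
  words <- c(words, 0L)
  words[words > 32767L] <- words[words > 32767L] - 65536L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  invisible(path)
}

read_annotations <- function(path, beat_codes = mit_beat_codes()) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  words <- readBin(con, "integer", n = max(1, sz / 2), size = 2L,
                   signed = FALSE, endian = "little")
  peaks <- integer(0)
  cur <- 0; pend <- 0; i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    if (w == 0L) break
    code <- w %/% 1024L
    delta <- w %% 1024L
    if (code == 59L) {
      pend <- pend + words[i + 1L] * 65536 + words[i + 2L]
      i <- i + 3L
      next
    }
    cur <- cur + delta + pend
    pend <- 0
    if (code %in% beat_codes) peaks <- c(peaks, cur + 1L)  # back to 1-based
    i <- i + 1L
  }
  as.integer(peaks)
}

# ---- WFDB signal files ------------------------------------------------------

#' Write an ECG record as WFDB-compatible files
#'
#' Emits a text header (`.hea`), a format-16 (16-bit little-endian,
#' sample-interleaved) signal file (`.dat`), and an MIT-format beat annotation
#' file.  Signals are quantized with the given gain, so
#' `read_record(write_record(r))` reproduces `r` up to one quantization step
#' (`1/(2*gain)`) and exactly on annotations and channel names.
#'
#' @param record An [ecg_record()].
#' @param out_dir Output directory (created if needed).
#' @param gain ADC units per physical unit.
#' @param ann_ext Annotation file extension.
#' @return Invisibly, the paths written (`header`, `dat`, `ann`).
#' @export
write_record <- function(record, out_dir, gain = 2000, ann_ext = "atr") {
  validate_ecg_record(record)
  ok <- dir.exists(out_dir) ||
    tryCatch(dir.create(out_dir, recursive = TRUE),
             warning = function(w) FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop_io(sprintf("cannot write to directory '%s'", out_dir))
  id <- record$record_id
  C <- nrow(record$signals); n <- ncol(record$signals)
  dig <- round(record$signals * gain)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767
  storage.mode(dig) <- "integer"

  dat_path <- file.path(out_dir, paste0(id, ".dat"))
  con <- file(dat_path, "wb")
  writeBin(as.vector(dig), con, size = 2L, endian = "little")  # interleaved
  close(con)

  chk <- as.integer(rowSums(dig) %% 65536)
  chk[chk > 32767L] <- chk[chk > 32767L] - 65536L
  hea_path <- file.path(out_dir, paste0(id, ".hea"))
  lines <- c(
    sprintf("%s %d %g %d", id, C, record$fs, n),
    sprintf("%s.dat 16 %g/mV 16 0 %d %d 0 %s", id, gain, dig[, 1], chk,
            record$channel_names))
  writeLines(lines, hea_path)

  ann_path <- file.path(out_dir, paste0(id, ".", ann_ext))
  write_annotations(ann_path, record$r_peaks)
  invisible(list(header = hea_path, dat = dat_path, ann = ann_path))
}

parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1) stop_format(sprintf("empty header '%s'", hea_path))
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop_format(sprintf("malformed header '%s'", hea_path))
  nsig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))
  nsamp <- as.integer(top[4])
  if (is.na(nsig) || nsig < 1) stop_format("header declares zero channels")
  if (is.na(nsamp) || nsamp < 1) stop_format("header declares zero samples")
  sig <- lapply(seq_len(nsig), function(i) {
    tk <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", tk[3])))
    if (is.na(gain) || gain == 0) gain <- 200           # WFDB default gain
    list(file = tk[1], format = sub("[^0-9].*$", "", tk[2]), gain = gain,
         name = if (length(tk) >= 9) paste(tk[9:length(tk)], collapse = " ")
                else sprintf("ch%d", i))
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a WFDB-compatible ECG record
#'
#' Parses the header and format-16 signal file, selects leads I, II, III by
#' case-insensitive name match (falling back, with a warning, to the first
#' three channels when the names are absent), and reads the beat annotations
#' as R-peak locations.
#'
#' @param signal_path Path to the `.hea` header (or the record base path).
#' @param annotation_path Path to the annotation file.
#' @param subject_id Optional subject id; defaults to the record name.
#' @param field_strength Field-strength tag for the returned record.
#' @param beat_codes Annotation codes accepted as beats (defaults to the MIT
#'   beat-class codes).
#' @return An [ecg_record()] with exactly three channels.
#' @export
read_record <- function(signal_path, annotation_path, subject_id = NULL,
                        field_strength = "synthetic",
                        beat_codes = mit_beat_codes()) {
  hea <- signal_path
  if (!file.exists(hea) && file.exists(paste0(hea, ".hea")))
    hea <- paste0(hea, ".hea")
  if (!file.exists(hea))
    stop_io(sprintf("signal header not found: '%s'", signal_path))
  hdr <- parse_header(hea)
  if (any(vapply(hdr$signals, function(s) s$format != "16", logical(1))))
    stop_format("only WFDB signal format 16 is supported")

  dat_path <- file.path(dirname(hea), hdr$signals[[1]]$file)
  if (!file.exists(dat_path))
    stop_io(sprintf("signal file not found: '%s'", dat_path))
  con <- file(dat_path, "rb")
  raw <- readBin(con, "integer", n = hdr$nsig * hdr$nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  close(con)
  if (length(raw) < hdr$nsig * hdr$nsamp)
    stop_format(sprintf("'%s' is shorter than the header declares", dat_path))
  dig <- matrix(raw, nrow = hdr$nsig)
  gains <- vapply(hdr$signals, `[[`, numeric(1), "gain")
  sig <- dig / gains
  names_all <- vapply(hdr$signals, `[[`, character(1), "name")

  want <- c("I", "II", "III")
  idx <- match(want, toupper(trimws(names_all)))
  if (anyNA(idx)) {
    if (hdr$nsig < 3)
      stop_format(sprintf("record '%s' has %d channels; 3 required",
                          hdr$record, hdr$nsig))
    warning(sprintf(
      "record '%s': leads I/II/III not identifiable by name; using the first three channels",
      hdr$record))
    idx <- 1:3
  }
  sig <- sig[idx, , drop = FALSE]
  ch <- if (anyNA(match(want, toupper(trimws(names_all))))) names_all[idx]
        else want

  if (!file.exists(annotation_path))
    stop_annotation(sprintf("annotation file not found: '%s'",
                            annotation_path))
  peaks <- read_annotations(annotation_path, beat_codes)
  if (length(peaks) == 0)
    stop_annotation(sprintf("no beat annotations in '%s'", annotation_path))

  ecg_record(record_id = hdr$record,
             subject_id = subject_id %||% hdr$record,
             field_strength = field_strength, fs = hdr$fs, signals = sig,
             channel_names = ch, r_peaks = peaks)
}

#' Load a dataset of records listed in a manifest
#'
#' The manifest (CSV with columns `record`, `subject`, `field_strength`)
#' carries the subject grouping that WFDB headers do not reliably provide.
#' Record paths are relative to `root` (base name without extension).
#'
#' @param root Dataset directory containing the manifest and record files.
#' @param field_strength Which field strength to load (`"3T"`, `"7T"`,
#'   `"synthetic"`); records of other strengths are ignored.
#' @param manifest Manifest file name within `root`.
#' @param ann_ext Annotation extension.
#' @param beat_codes Accepted beat annotation codes.
#' @return List of [ecg_record()]s, deterministically ordered by `record_id`.
#' @export
load_dataset <- function(root, field_strength, manifest = "manifest.csv",
                         ann_ext = "atr", beat_codes = mit_beat_codes()) {
  mpath <- file.path(root, manifest)
  if (!file.exists(mpath)) stop_io(sprintf("manifest not found: '%s'", mpath))
  mf <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("record", "subject", "field_strength")
  if (!all(need %in% names(mf)))
    stop_format(sprintf("manifest must have columns %s",
                        paste(need, collapse = ", ")))
  sel <- mf[mf$field_strength == field_strength, , drop = FALSE]
  if (nrow(sel) == 0)
    stop_config(sprintf(
      "no records with field_strength '%s' in '%s'; manifest contains: %s",
      field_strength, mpath,
      paste(sort(unique(mf$field_strength)), collapse = ", ")))
  sel <- sel[order(sel$record), , drop = FALSE]
  recs <- lapply(seq_len(nrow(sel)), function(i) {
    base <- file.path(root, sel$record[i])
    read_record(paste0(base, ".hea"), paste0(base, ".", ann_ext),
                subject_id = sel$subject[i],
                field_strength = field_strength, beat_codes = beat_codes)
  })
  recs[order(vapply(recs, `[[`, character(1), "record_id"))]
}
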