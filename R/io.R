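# Readers and writers for the EEG container formats the pipeline consumes:
# plain CSV (one column per channel) with a sidecar metadata table, EDF
# (16-bit European Data Format), and BrainVision (.vhdr/.eeg triplets).

#' Write a recording as CSV
#'
#' One column per channel, header row with channel names. Sampling rate and
#' label travel in a sidecar table (see [write_cohort()]) or are passed back
#' to [read_recording()] explicitly.
#'
#' @param recording A `ctesm_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  # %.17g round-trips IEEE doubles exactly
  df <- as.data.frame(lapply(as.data.frame(recording$signal),
                             function(col) sprintf("%.17g", col)))
  names(df) <- colnames(recording$signal)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a recording as EDF
#'
#' Minimal standard-conformant EDF: 16-bit samples, 1-second data records.
#' The sampling rate must be a positive integer and trailing samples that do
#' not fill a whole record are dropped. Physical scaling is chosen per
#' channel from the data range, so the round trip is exact to 16-bit
#' quantization.
#'
#' @inheritParams write_recording_csv
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(recording, path) {
  fs <- recording$sampling_rate_hz
  if (fs != round(fs)) {
    stop_validation("EDF writer requires an integer sampling rate")
  }
  fs <- as.integer(fs)
  sig <- recording$signal
  nc <- ncol(sig)
  n_rec <- floor(nrow(sig) / fs)
  if (n_rec < 1L) stop_validation("recording shorter than one EDF record (1 s)")
  sig <- sig[seq_len(n_rec * fs), , drop = FALSE]

  pmax_ <- apply(abs(sig), 2, max)
  pmax_[pmax_ == 0] <- 1
  dig_max <- 32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(recording$subject_id %||% "X", 80),
    pad(paste0("label=", recording$label %||% "NA"), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (nc + 1), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(nc, 4)
  )
  chn <- colnames(sig) %||% sprintf("Ch%02d", seq_len(nc))
  hdr <- paste0(
    hdr,
    paste(pad(substr(chn, 1, 16), 16), collapse = ""),
    paste(rep(pad("", 80), nc), collapse = ""),
    paste(rep(pad("uV", 8), nc), collapse = ""),
    paste(pad(sprintf("%.6g", -pmax_), 8), collapse = ""),
    paste(pad(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(rep(pad(-dig_max, 8), nc), collapse = ""),
    paste(rep(pad(dig_max, 8), nc), collapse = ""),
    paste(rep(pad("", 80), nc), collapse = ""),
    paste(rep(pad(fs, 8), nc), collapse = ""),
    paste(rep(pad("", 32), nc), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  dig <- sweep(sig, 2, dig_max / pmax_, "*")
  dig <- matrix(as.integer(round(dig)), nrow(sig), nc)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < w) {
      stop_format(sprintf("truncated EDF header in '%s'", path))
    }
    trimws(raw)
  }
  rd(8)                      # version
  sid <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8)               # date, time
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(dur) || is.na(nc) || nc < 1L) {
    stop_format(sprintf("unparseable EDF header in '%s'", path))
  }
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)          # transducer
  for (i in seq_len(nc)) rd(8)           # phys dim
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  for (i in seq_len(nc)) rd(80)          # prefilter
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), character(1)))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop_format("EDF files with per-channel sampling rates are not supported")
  }
  fs <- spr[1] / dur
  total <- n_rec * spr[1] * nc
  dat <- readBin(con, integer(), n = total, size = 2L, endian = "little")
  if (length(dat) < total) {
    stop_format(sprintf("truncated EDF data section in '%s'", path))
  }
  sig <- matrix(0, n_rec * spr[1], nc)
  idx <- 0L
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(nc)) {
      sig[rows, ch] <- dat[(idx + 1L):(idx + spr[1])]
      idx <- idx + spr[1]
    }
  }
  scale_ <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (ch in seq_len(nc)) {
    sig[, ch] <- pmin_[ch] + (sig[, ch] - dmin_[ch]) * scale_[ch]
  }
  colnames(sig) <- labels
  label <- if (grepl("^label=", recinfo)) sub("^label=", "", recinfo) else NA
  new_recording(sig, fs, label, sid)
}

#' Write a recording in BrainVision format
#'
#' Emits the `.vhdr` header, `.vmrk` marker stub and `.eeg` binary
#' (multiplexed IEEE float32) files.
#'
#' @inheritParams write_recording_csv
#' @param path Path of the `.vhdr` file; the `.eeg`/`.vmrk` companions are
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_recording_brainvision <- function(recording, path) {
  stem <- sub("\\.vhdr$", "", path)
  eeg <- paste0(stem, ".eeg")
  vmrk <- paste0(stem, ".vmrk")
  nc <- ncol(recording$signal)
  chn <- colnames(recording$signal) %||% sprintf("Ch%02d", seq_len(nc))
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nc),
    sprintf("SamplingInterval=%.10g", 1e6 / recording$sampling_rate_hz),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nc), chn)
  )
  writeLines(hdr, path)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Marker Infos]"), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$signal)), con, size = 4L, endian = "little")
  invisible(path)
}

read_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop_format(sprintf("BrainVision header lacks %s", key))
    sub(paste0("^", key, "="), "", hit[1])
  }
  fmt <- getval("BinaryFormat")
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    stop_format(sprintf("unsupported BrainVision BinaryFormat '%s'", fmt))
  }
  if (getval("DataOrientation") != "MULTIPLEXED") {
    stop_format("only MULTIPLEXED BrainVision data supported")
  }
  nc <- as.integer(getval("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getval("SamplingInterval"))
  datafile <- file.path(dirname(path), getval("DataFile"))
  if (!file.exists(datafile)) {
    stop_format(sprintf("BrainVision data file '%s' missing", datafile))
  }
  chlines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  chn <- vapply(strsplit(sub("^Ch[0-9]+=", "", chlines), ","),
                `[`, character(1), 1)
  sz <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_total <- file.info(datafile)$size / sz
  if (n_total != floor(n_total) || (n_total %% nc) != 0) {
    stop_format(sprintf("BrainVision data size inconsistent with %d channels", nc))
  }
  con <- file(datafile, "rb")
  on.exit(close(con))
  dat <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, numeric(), n = n_total, size = 4L, endian = "little")
  } else {
    readBin(con, integer(), n = n_total, size = 2L, endian = "little")
  }
  sig <- t(matrix(dat, nc, n_total / nc))
  if (length(chn) == nc) colnames(sig) <- chn
  new_recording(sig, fs, NA, sub("\\.vhdr$", "", basename(path)))
}

#' Read a recording from disk
#'
#' Dispatches on extension (or an explicit `format`): `.edf`, `.vhdr`
#' (BrainVision) or `.csv`. CSV files carry no metadata of their own; the
#' sampling rate comes from the cohort sidecar table or from
#' `sampling_rate_hz`.
#'
#' @param path Input file.
#' @param format Optional format hint: `"csv"`, `"edf"` or `"brainvision"`.
#' @param sampling_rate_hz Sampling rate for CSV input (ignored otherwise).
#' @param sidecar Optional path to a sidecar CSV (columns `subject_id`,
#'   `label`, `sampling_rate_hz`, `file`) from which CSV metadata is taken.
#' @param label Optional class label for CSV input.
#' @return A `ctesm_recording`.
#' @export
read_recording <- function(path, format = NULL, sampling_rate_hz = NULL,
                           sidecar = NULL, label = NA) {
  if (!file.exists(path)) stop_format(sprintf("file '%s' does not exist", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", vhdr = "brainvision", csv = "csv",
                     stop_format(sprintf(
                       "cannot infer format of '%s'; pass `format`", path)))
  }
  switch(format,
    edf = read_edf(path),
    brainvision = read_brainvision(path),
    csv = {
      sid <- sub("\\.csv$", "", basename(path))
      if (!is.null(sidecar)) {
        meta <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
        row <- meta[meta$file == basename(path) | meta$subject_id == sid, ]
        if (nrow(row) == 1L) {
          sampling_rate_hz <- row$sampling_rate_hz
          label <- row$label
          sid <- row$subject_id
        }
      }
      if (is.null(sampling_rate_hz)) {
        stop_config(sprintf(
          "CSV input '%s' needs a sampling rate (sidecar or sampling_rate_hz)",
          path))
      }
      df <- utils::read.csv(path, check.names = FALSE)
      if (!nrow(df) || !all(vapply(df, is.numeric, logical(1)))) {
        stop_format(sprintf("'%s' is not a numeric channel matrix", path))
      }
      new_recording(as.matrix(df), sampling_rate_hz, label, sid)
    },
    stop_format(sprintf("unknown format '%s'", format))
  )
}

#' Write a cohort to a directory
#'
#' One file per recording plus a `sidecar.csv` with columns `subject_id`,
#' `label`, `sampling_rate_hz`, `file`.
#'
#' @param cohort A `ctesm_cohort` or list of recordings.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @return The sidecar path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    r <- cohort[[i]]
    files[i] <- paste0(r$subject_id, ".", format)
    fp <- file.path(dir, files[i])
    if (format == "csv") write_recording_csv(r, fp) else write_recording_edf(r, fp)
  }
  sidecar <- file.path(dir, "sidecar.csv")
  utils::write.csv(data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, character(1)),
    label = cohort_labels(cohort),
    sampling_rate_hz = vapply(cohort, function(r) r$sampling_rate_hz, numeric(1)),
    file = files, stringsAsFactors = FALSE
  ), sidecar, row.names = FALSE)
  invisible(sidecar)
}
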