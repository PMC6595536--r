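# Minimal EDF (European Data Format, 16-bit) writer and reader.
# Covers the plain-EDF subset polysomnography exports use: fixed-length data
# records of little-endian 2-byte integers with per-signal linear scaling.
# No EDF+ annotations, no discontinuous records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'", call. = FALSE)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  for (digits in seq(7, 1)) {
    s <- formatC(signif(x, digits), format = "g", digits = digits)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("cannot format ", x, " in ", width, " chars", call. = FALSE)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records; each channel is scaled to its
#' own symmetric physical range, so round-trip error is at most half a
#' quantisation step, `max(abs(x)) / 32767 / 2`. The recording is
#' zero-padded to a whole number of records.
#'
#' @param recording An `eeg_recording`; sampling rate must be an integer.
#' @param path Output path.
#' @param physical_dimension Unit string stored per signal (default `"uV"`).
#' @export
write_edf <- function(recording, path, physical_dimension = "uV") {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  chans <- recording$channels
  ns <- length(chans)
  n_rec <- ceiling(recording$n_samples / fs)
  n_pad <- n_rec * fs - recording$n_samples
  # symmetric physical range per channel, fixed to the exact value the
  # 8-char header field can carry so writer and reader scaling agree
  pmin_str <- vapply(chans, function(x) {
    m <- max(abs(x)); if (m == 0) m <- 1
    edf_num(-m * (1 + 1e-6), 8)
  }, character(1))
  pmax_ <- abs(as.numeric(pmin_str))
  pmax_str <- vapply(pmax_, edf_num, character(1), width = 8)
  if (any(abs(as.numeric(pmax_str) + as.numeric(pmin_str)) > 0))
    stop("EDF physical range formatting mismatch", call. = FALSE)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80), edf_pad("apneaband export", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8), edf_pad(hdr_bytes, 8),
    edf_pad("", 44), edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(vapply(names(chans), edf_pad, character(1), width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),                   # transducer
    paste(rep(edf_pad(physical_dimension, 8), ns), collapse = ""),
    paste(pmin_str, collapse = ""),
    paste(pmax_str, collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),                   # prefilter
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # inverse of the reader's (d - dig_min) * gain + phys_min mapping
  dig <- lapply(seq_len(ns), function(i) {
    x <- c(chans[[i]], numeric(n_pad))
    gain <- 2 * pmax_[i] / 65535
    as.integer(round((x + pmax_[i]) / gain) - 32768L)
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width) {
  r <- readBin(con, "raw", width)
  s <- rawToChar(r[r != as.raw(0)])
  Encoding(s) <- "latin1"   # header bytes need not be valid UTF-8
  trimws(s)
}

#' Read an EDF file
#'
#' @param path Path to a 16-bit EDF file (all signals must share one
#'   sampling rate).
#' @return An `eeg_recording` with channel labels from the EDF header and
#'   samples in physical units.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("unreadable EDF header: file too short", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8)
  if (version != "0") stop("unreadable EDF header: bad version field '", version, "'", call. = FALSE)
  invisible(readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE))
  hdr_bytes <- as.integer(read_edf_field(con, 8))
  invisible(readChar(con, 44, useBytes = TRUE))
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header: bad signal count", call. = FALSE)
  rd <- function(w) vapply(seq_len(ns), function(i) read_edf_field(con, w), character(1))
  labels   <- rd(16); invisible(rd(80)); invisible(rd(8))
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min  <- as.numeric(rd(8)); dig_max  <- as.numeric(rd(8))
  invisible(rd(80))
  spr <- as.integer(rd(8))
  invisible(rd(32))
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only", call. = FALSE)
  fs <- spr[1] / rec_dur
  expect_sz <- hdr_bytes + 2 * n_rec * sum(spr)
  if (sz < expect_sz) stop("EDF data truncated (", sz, " < ", expect_sz, " bytes)", call. = FALSE)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  chans <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little", signed = TRUE)
      chans[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (d - dig_min[i]) * gain[i] + phys_min[i]
    }
  }
  names(chans) <- labels
  new_recording(chans, fs)
}
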