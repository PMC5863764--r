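# Minimal EDF (European Data Format) reader/writer for polysomnography
# fixtures: one continuous multi-channel EEG, 16-bit samples, 1-second data
# records, all channels at the same rate. Physical units are microvolts.
# The full recording must therefore contain a whole number of seconds;
# write_edf() truncates trailing partial seconds with a warning.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a multi-channel signal as EDF
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (samples per 1-s data record).
#' @param labels channel labels, one per row of `signal`.
#' @param path output file path.
#' @param start_time POSIXct recording start (defaults to a fixed epoch so
#'   fixtures are byte-stable).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, fs, labels, path,
                      start_time = as.POSIXct("2000-01-01 23:00:00", tz = "UTC")) {
  if (!is.matrix(signal)) stop("write_edf: signal must be channels x samples matrix")
  nch <- nrow(signal)
  if (length(labels) != nch) stop("write_edf: one label per channel required")
  n_rec <- floor(ncol(signal) / fs)
  if (n_rec < 1L) stop("write_edf: signal shorter than one data record")
  if (n_rec * fs < ncol(signal)) {
    warning("write_edf: truncating trailing partial second")
    signal <- signal[, seq_len(n_rec * fs), drop = FALSE]
  }
  phys_max <- max(1, ceiling(max(abs(signal))))
  phys_min <- -phys_max
  dig_max <- 32767L; dig_min <- -32768L
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    format(start_time, "%d.%m.%y"),
    format(start_time, "%H.%M.%S"),
    edf_pad(256 * (1 + nch), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(nch, 4),
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("AgAgCl electrode", 80), nch), collapse = ""),
    paste(rep(edf_pad("uV", 8), nch), collapse = ""),
    paste(rep(edf_pad(phys_min, 8), nch), collapse = ""),
    paste(rep(edf_pad(phys_max, 8), nch), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), nch), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad(fs, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 32), nch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  dig <- round((signal - phys_min) / scale) + dig_min
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports continuous EDF with identical sampling rate across channels.
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix, microvolts),
#'   `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(fixed, 237, 244))
  rec_dur <- as.numeric(substr(fixed, 245, 252))
  nch <- as.integer(substr(fixed, 253, 256))
  fld <- function(width) {
    raw <- readChar(con, width * nch, useBytes = TRUE)
    trimws(substring(raw, (seq_len(nch) - 1L) * width + 1L, seq_len(nch) * width))
  }
  labels <- fld(16)
  fld(80)                      # transducer
  units <- fld(8)
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                      # prefiltering
  ns <- as.integer(fld(8))
  fld(32)                      # reserved
  if (length(unique(ns)) != 1L)
    stop("read_edf: heterogeneous sampling rates not supported")
  fs <- ns[1L] / rec_dur
  if (fs != round(fs)) stop("read_edf: non-integer sampling rate")
  raw <- readBin(con, "integer", n = n_rec * nch * ns[1L], size = 2L,
                 signed = TRUE, endian = "little")
  arr <- array(raw, dim = c(ns[1L], nch, n_rec))
  sig <- matrix(0, nrow = nch, ncol = n_rec * ns[1L])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (ch in seq_len(nch)) {
    sig[ch, ] <- as.numeric(arr[, ch, ]) * scale[ch] +
      (phys_min[ch] - dig_min[ch] * scale[ch])
  }
  rownames(sig) <- labels
  list(signal = sig, fs = as.integer(round(fs)), labels = labels,
       units = units)
}
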