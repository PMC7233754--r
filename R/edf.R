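# Minimal EDF (European Data Format) signal I/O.
#
# EDF is the standard portable container for biosignal recordings: a fixed
# 256-byte ASCII header, 256 ASCII bytes per signal, then fixed-duration
# data records of 16-bit little-endian integers per signal. This writer
# emits one signal per channel in microvolts with 1-second records; the
# 16-bit digital range over the device's physical range keeps the
# round-trip error well below one ADC step of the emulated headset.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) pad_ascii(format(x, trim = TRUE, scientific = FALSE), width)

#' Write a recording as an EDF file
#'
#' One EDF signal per channel, physical dimension uV, 1-second data records
#' (the trailing record is zero-padded when the recording is not an integral
#' number of seconds). The physical range is the device's dynamic range, the
#' digital range the full 16-bit span, so samples round-trip to within
#' 8400/65535 ~ 0.13 uV — under one LSB of the emulated ADC.
#'
#' @param recording a `raw_recording` (rate must be an integer).
#' @param path output file path.
#' @param profile a `device_profile` providing the physical range.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, profile = epoc_default_profile()) {
  stopifnot(inherits(recording, "raw_recording"),
            recording$rate_hz == round(recording$rate_hz))
  ns <- length(recording$channel_labels)
  spr <- as.integer(recording$rate_hz)          # samples per 1 s record
  nsamp <- ncol(recording$samples)
  nrec <- as.integer(ceiling(nsamp / spr))
  pmin <- -profile$dynamic_range_uVpp / 2
  pmax <- profile$dynamic_range_uVpp / 2
  dmin <- -32768L; dmax <- 32767L
  start <- as.POSIXct(recording$start_time_s, origin = "1970-01-01", tz = "UTC")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_ascii("0", 8))
  wr(pad_ascii("X X X X", 80))                  # local patient id
  wr(pad_ascii("Startdate X X X X", 80))        # local recording id
  wr(format(start, "%d.%m.%y"))
  wr(format(start, "%H.%M.%S"))
  wr(edf_num(256L * (1L + ns), 8))
  wr(pad_ascii("", 44))
  wr(edf_num(nrec, 8))
  wr(edf_num(1L, 8))                            # record duration, seconds
  wr(edf_num(ns, 4))
  for (lab in recording$channel_labels) wr(pad_ascii(lab, 16))
  for (i in seq_len(ns)) wr(pad_ascii("EEG electrode", 80))
  for (i in seq_len(ns)) wr(pad_ascii("uV", 8))
  for (i in seq_len(ns)) wr(edf_num(pmin, 8))
  for (i in seq_len(ns)) wr(edf_num(pmax, 8))
  for (i in seq_len(ns)) wr(edf_num(dmin, 8))
  for (i in seq_len(ns)) wr(edf_num(dmax, 8))
  for (i in seq_len(ns)) wr(pad_ascii(sprintf("HP:%gHz LP:%gHz",
                                              profile$bandwidth_hz[1],
                                              profile$bandwidth_hz[2]), 80))
  for (i in seq_len(ns)) wr(edf_num(spr, 8))
  for (i in seq_len(ns)) wr(pad_ascii("", 32))

  scale <- (dmax - dmin) / (pmax - pmin)
  padded <- matrix(0, ns, nrec * spr)
  padded[, seq_len(nsamp)] <- recording$samples
  dig <- round((padded - pmin) * scale) + dmin
  dig[dig > dmax] <- dmax; dig[dig < dmin] <- dmin
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, cols]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain EDF)
#'
#' @param path EDF file path.
#' @param n_samples optional true sample count, to strip the zero padding of
#'   a non-integral final record.
#' @return a `raw_recording` (marked quantized: samples sit on the EDF
#'   digital grid).
#' @export
read_edf <- function(path, n_samples = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) stop_cs("malformed EDF: truncated header in '%s'", path)
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop_cs("malformed EDF '%s': bad version record '%s' at byte 0", path, version)
  rd(80); rd(80)
  date <- rd(8); time <- rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop_cs("malformed EDF '%s': bad signal count at byte 252", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop_cs("EDF '%s' has per-signal sampling rates; not supported", path)
  }
  out <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2L, endian = "little")
      if (length(v) < spr[s]) {
        stop_cs("malformed EDF '%s': truncated at data record %d, signal %d",
                path, r, s)
      }
      out[s, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (v - dmin[s]) / (dmax[s] - dmin[s]) * (pmax[s] - pmin[s]) + pmin[s]
    }
  }
  if (!is.null(n_samples)) out <- out[, seq_len(n_samples), drop = FALSE]
  dt <- strptime(paste(date, time), "%d.%m.%y %H.%M.%S", tz = "UTC")
  start_s <- if (is.na(dt)) 0 else as.numeric(dt)
  new_raw_recording(start_s, spr[1] / recdur, labels, out, quantized = TRUE)
}
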