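#' Device profiles
#'
#' A `device_profile` is an immutable description of an EEG headset: its
#' montage (ordered 10-10 electrode labels and reference positions), internal
#' and output sampling rates, ADC quantization (microvolts per least
#' significant bit and bit depth), analog bandwidth, mains notch filters and
#' peak-to-peak dynamic range. Every signal-generating and signal-consuming
#' function in the package is parameterised by a profile, so other headsets
#' can be described without touching the pipeline.
#'
#' @param name device name.
#' @param channel_labels ordered character vector of 10-10 electrode positions.
#' @param reference_labels character vector of reference positions.
#' @param internal_rate_hz internal ADC sampling rate (Hz).
#' @param output_rate_hz rate of the emitted stream (Hz); must divide
#'   `internal_rate_hz` evenly.
#' @param lsb_uV microvolts per quantization step.
#' @param resolution_bits ADC resolution in bits.
#' @param bandwidth_hz length-2 numeric `(low, high)` analog bandwidth in Hz.
#' @param notch_hz numeric vector of mains notch frequencies (Hz).
#' @param dynamic_range_uVpp peak-to-peak dynamic range in microvolts.
#'
#' @return an object of class `device_profile`.
#' @export
device_profile <- function(name, channel_labels, reference_labels,
                           internal_rate_hz, output_rate_hz,
                           lsb_uV, resolution_bits,
                           bandwidth_hz, notch_hz, dynamic_range_uVpp) {
  p <- structure(list(
    name = as.character(name),
    channel_labels = as.character(channel_labels),
    reference_labels = as.character(reference_labels),
    internal_rate_hz = as.numeric(internal_rate_hz),
    output_rate_hz = as.numeric(output_rate_hz),
    lsb_uV = as.numeric(lsb_uV),
    resolution_bits = as.integer(resolution_bits),
    bandwidth_hz = as.numeric(bandwidth_hz),
    notch_hz = as.numeric(notch_hz),
    dynamic_range_uVpp = as.numeric(dynamic_range_uVpp)
  ), class = "device_profile")
  validate_device_profile(p)
  p
}

#' Validate a device profile's invariants
#'
#' Checks that the output rate divides the internal rate evenly, that the
#' bandwidth is an increasing pair below the output Nyquist frequency, and
#' that the advertised dynamic range agrees with `lsb_uV * 2^resolution_bits`
#' to within 2% (consumer-headset data sheets round the advertised range, so
#' exact equality is deliberately not required).
#'
#' @param p a `device_profile`.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_device_profile <- function(p) {
  stopifnot(inherits(p, "device_profile"))
  if (length(p$channel_labels) < 1L || anyDuplicated(p$channel_labels)) {
    stop_cs("channel_labels must be a non-empty set of unique positions")
  }
  if (p$internal_rate_hz <= 0 || p$output_rate_hz <= 0) {
    stop_cs("sampling rates must be positive")
  }
  if (p$internal_rate_hz %% p$output_rate_hz != 0) {
    stop_cs("output_rate_hz (%g) must divide internal_rate_hz (%g) evenly",
            p$output_rate_hz, p$internal_rate_hz)
  }
  if (length(p$bandwidth_hz) != 2L || p$bandwidth_hz[1] >= p$bandwidth_hz[2]) {
    stop_cs("bandwidth_hz must be an increasing (low, high) pair")
  }
  if (p$bandwidth_hz[2] >= p$output_rate_hz / 2) {
    stop_cs("bandwidth high edge (%g Hz) must lie below the output Nyquist (%g Hz)",
            p$bandwidth_hz[2], p$output_rate_hz / 2)
  }
  if (p$lsb_uV <= 0 || p$resolution_bits <= 0 || p$dynamic_range_uVpp <= 0) {
    stop_cs("quantization parameters must be positive")
  }
  implied <- p$lsb_uV * 2^p$resolution_bits
  if (abs(implied - p$dynamic_range_uVpp) / p$dynamic_range_uVpp > 0.02) {
    stop_cs("dynamic_range_uVpp (%g) disagrees with lsb * 2^bits (%g) by more than 2%%",
            p$dynamic_range_uVpp, implied)
  }
  invisible(p)
}

#' Default EPOC-class headset profile
#'
#' The profile of the most widely used consumer 14-channel saline-electrode
#' headset: electrodes at AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4,
#' F8, AF4 with references at P3/P4, 2048 Hz internal sampling downsampled to
#' a 128 Hz stream, 14-bit resolution at 0.51 uV per LSB, 0.16-43 Hz
#' bandwidth, 50/60 Hz digital notches and an 8400 uV peak-to-peak range.
#'
#' @return a `device_profile`.
#' @examples
#' p <- epoc_default_profile()
#' length(p$channel_labels)  # 14
#' p$output_rate_hz          # 128
#' @export
epoc_default_profile <- function() {
  device_profile(
    name = "EPOC",
    channel_labels = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                       "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
    reference_labels = c("P3", "P4"),
    internal_rate_hz = 2048,
    output_rate_hz = 128,
    lsb_uV = 0.51,
    resolution_bits = 14,
    bandwidth_hz = c(0.16, 43),
    notch_hz = c(50, 60),
    dynamic_range_uVpp = 8400
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s\n", x$name))
  cat(sprintf("  %d channels: %s\n", length(x$channel_labels),
              paste(x$channel_labels, collapse = " ")))
  cat(sprintf("  references: %s\n", paste(x$reference_labels, collapse = " ")))
  cat(sprintf("  %g Hz internal -> %g Hz output, %d-bit @ %g uV/LSB, range %g uVpp\n",
              x$internal_rate_hz, x$output_rate_hz, x$resolution_bits,
              x$lsb_uV, x$dynamic_range_uVpp))
  cat(sprintf("  bandwidth %g-%g Hz, notches %s Hz\n",
              x$bandwidth_hz[1], x$bandwidth_hz[2],
              paste(x$notch_hz, collapse = "/")))
  invisible(x)
}

#' Write or read a device profile as JSON
#'
#' @param p a `device_profile`.
#' @param path file path.
#' @return `read_device_profile` returns a `device_profile`;
#'   `write_device_profile` returns `path` invisibly.
#' @export
write_device_profile <- function(p, path) {
  validate_device_profile(p)
  write_json_file(unclass(p), path)
}

#' @rdname write_device_profile
#' @export
read_device_profile <- function(path) {
  x <- read_json_file(path)
  device_profile(x$name, x$channel_labels, x$reference_labels,
                 x$internal_rate_hz, x$output_rate_hz, x$lsb_uV,
                 x$resolution_bits, x$bandwidth_hz, x$notch_hz,
                 x$dynamic_range_uVpp)
}
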