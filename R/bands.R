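#' Frequency bands
#'
#' EEG analysis in this package bins spectra into the four classical rhythms:
#' theta (4-8 Hz), alpha (8-12 Hz), beta (12-30 Hz) and gamma (30-43 Hz).
#' Band intervals are half-open `[low, high)` so every frequency belongs to
#' at most one band; the gamma ceiling is clipped at the 43 Hz analog
#' bandwidth of the default headset. `default_bands()` tiles `[4, 43)` Hz
#' with no gaps or overlaps.
#'
#' @return a data.frame with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' default_bands()
#' @export
default_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma"),
    low_hz = c(4, 8, 12, 30),
    high_hz = c(8, 12, 30, 43),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz <= 0) || any(bands$low_hz >= bands$high_hz)) {
    stop_cs("each band needs 0 < low_hz < high_hz")
  }
  b <- bands[order(bands$low_hz), ]
  if (nrow(b) > 1L && any(b$high_hz[-nrow(b)] > b$low_hz[-1] + 1e-12)) {
    stop_cs("bands overlap; intervals must be disjoint")
  }
  invisible(bands)
}

#' Map a frequency to its band
#'
#' Bands are half-open `[low, high)`: 8 Hz belongs to alpha, not theta.
#'
#' @param frequency_hz a single frequency in Hz.
#' @param bands band table as from [default_bands()]; must be non-overlapping.
#' @return the band name, or `NA_character_` if the frequency falls in no band.
#' @examples
#' band_of(6)   # "theta"
#' band_of(8)   # "alpha"
#' band_of(50)  # NA
#' @export
band_of <- function(frequency_hz, bands = default_bands()) {
  validate_bands(bands)
  stopifnot(is.numeric(frequency_hz), length(frequency_hz) == 1L)
  hit <- bands$low_hz <= frequency_hz & frequency_hz < bands$high_hz
  if (!any(hit)) return(NA_character_)
  bands$name[which(hit)[1]]
}
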