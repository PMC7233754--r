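# Welch power spectral density estimation.
#
# Averaged modified periodograms with a periodic Hann window and fractional
# overlap, density-normalized so that the integral of the one-sided density
# over frequency equals the mean squared amplitude (Parseval). This makes
# band power of a pure sinusoid of amplitude A come out at A^2/2 regardless
# of where the tone falls relative to the frequency grid.

hann_window <- function(n) {
  # periodic Hann, the spectral-analysis convention
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

#' Welch power spectral density
#'
#' Estimates the one-sided power spectral density of each channel by
#' averaging Hann-windowed, overlapping, mean-detrended segments. The
#' density is in squared-amplitude units per Hz (uV^2/Hz for microvolt
#' signals): integrating it over all frequencies recovers the signal's mean
#' squared amplitude.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param rate_hz sampling rate in Hz.
#' @param window_s segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution at any rate).
#' @param overlap_fraction fractional overlap between segments (default 0.5).
#' @return a `welch_psd` object: list with `freq_hz` (vector) and `density`
#'   (channels x frequency matrix), plus the estimation parameters.
#' @examples
#' fs <- 128
#' t <- seq(0, 10 - 1/fs, by = 1/fs)
#' psd <- welch_psd(2 * sin(2 * pi * 10 * t), fs)
#' # total integrated power ~ A^2/2 = 2
#' sum(diff(psd$freq_hz)[1] * psd$density[1, ])
#' @export
welch_psd <- function(x, rate_hz, window_s = 2, overlap_fraction = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(is.matrix(x), rate_hz > 0, window_s > 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  nper <- round(window_s * rate_hz)
  nsamp <- ncol(x)
  if (nsamp < nper) {
    stop_cs("signal too short for Welch window: %d samples < %d (need >= %g s at %g Hz)",
            nsamp, nper, window_s, rate_hz)
  }
  step <- max(1L, round(nper * (1 - overlap_fraction)))
  starts <- seq(1L, nsamp - nper + 1L, by = step)
  w <- hann_window(nper)
  scale <- 1 / (rate_hz * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * rate_hz / nper
  nch <- nrow(x)
  # all (channel, segment) columns in one matrix -> a single mvfft call
  segs <- matrix(0, nrow = nper, ncol = nch * length(starts))
  k <- 0L
  for (s in starts) {
    seg <- x[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    segs[, k + seq_len(nch)] <- t(seg) * w
    k <- k + nch
  }
  ft <- stats::mvfft(segs)
  p <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2 * scale
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  p <- p * dbl
  # average periodograms per channel
  dens <- matrix(0, nrow = nch, ncol = nfreq)
  for (ci in seq_len(nch)) {
    cols <- seq(ci, ncol(p), by = nch)
    dens[ci, ] <- rowMeans(p[, cols, drop = FALSE])
  }
  structure(list(freq_hz = freq, density = dens, rate_hz = rate_hz,
                 window_s = window_s, overlap_fraction = overlap_fraction,
                 n_segments = length(starts)),
            class = "welch_psd")
}

#' Integrated band power from a Welch PSD
#'
#' Trapezoidal integral of the one-sided density over the half-open band
#' `[low_hz, high_hz)`, per channel, in squared-amplitude units (uV^2).
#'
#' @param psd a `welch_psd` object.
#' @param band either a band name from `bands`, or a list/row with `low_hz`
#'   and `high_hz`.
#' @param bands band table used to resolve a band name.
#' @return named numeric vector, one integrated power per channel.
#' @export
band_power <- function(psd, band, bands = default_bands()) {
  stopifnot(inherits(psd, "welch_psd"))
  if (is.character(band)) {
    row <- bands[bands$name == band, ]
    if (nrow(row) != 1L) stop_cs("unknown band '%s'", band)
    band <- as.list(row)
  }
  lo <- band$low_hz; hi <- band$high_hz
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  fmax <- max(psd$freq_hz)
  if (lo < min(psd$freq_hz) - 1e-9 || hi > fmax + 1e-9) {
    stop_cs("band [%g, %g) outside PSD frequency range [0, %g]", lo, hi, fmax)
  }
  sel <- psd$freq_hz >= lo - 1e-12 & psd$freq_hz < hi - 1e-12
  if (sum(sel) < 2L) return(stats::setNames(rep(0, nrow(psd$density)),
                                            rownames(psd$density)))
  f <- psd$freq_hz[sel]
  apply(psd$density[, sel, drop = FALSE], 1L, function(d) trapz(f, d))
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("<welch_psd> %d channel(s), %d frequencies 0-%g Hz (df = %g), %d segment(s)\n",
              nrow(x$density), length(x$freq_hz), max(x$freq_hz),
              x$freq_hz[2] - x$freq_hz[1], x$n_segments))
  invisible(x)
}
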