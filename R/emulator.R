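# Synthetic EPOC-class EEG stream.
#
# The emulator replaces the physical headset: it renders a timeline into a
# continuous multichannel microvolt signal with known ground truth. Each
# channel is 1/f (pink) background noise plus one sinusoidal oscillator per
# frequency band whose amplitude tracks the task state (working-memory
# "onset" during non-practice displays/probes, "offset" during rests,
# "other" elsewhere); the signal is generated at the device's internal rate,
# band-pass and notch filtered with zero-phase (forward-backward)
# Butterworth filters, then decimated to the output rate.

new_raw_recording <- function(start_time_s, rate_hz, channel_labels, samples,
                              quantized = FALSE) {
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_labels))
  rownames(samples) <- channel_labels
  structure(list(start_time_s = as.numeric(start_time_s),
                 rate_hz = as.numeric(rate_hz),
                 channel_labels = as.character(channel_labels),
                 samples = samples,
                 quantized = isTRUE(quantized)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz,
              if (x$quantized) ", quantized" else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `raw_recording`.
#' @return numeric seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$rate_hz
}

#' Ground-truth generator parameters for one simulated participant
#'
#' Bundles everything that determines a participant's synthetic EEG: a
#' latent engagement trait (standard-normal scale), baseline oscillator
#' amplitudes per electrode and band, multiplicative task-state gains, an
#' optional coupling that ties one (electrode, band, state) amplitude to
#' engagement, and the pink-noise scale.
#'
#' The coupling multiplies the targeted amplitude by
#' `exp(coefficient * engagement)`, so positive coefficients make engaged
#' participants express more power in the coupled band — the mechanism that
#' produces recoverable brain-behavior correlations in simulated cohorts.
#'
#' @param profile a `device_profile`.
#' @param engagement latent trait value (standard-normal scale).
#' @param band_gains electrodes x bands matrix of baseline oscillator
#'   amplitudes in uV (rows named by electrode, columns by band), or `NULL`
#'   for defaults (theta 4, alpha 6, beta 2, gamma 1 uV everywhere).
#' @param state_modulation named list of `onset`/`offset`/`other`
#'   electrodes x bands gain matrices; defaults to all 1.
#' @param coupling `NULL`, or a list with `electrode`, `band`, `state`
#'   (`"any"` to couple in every state) and `coefficient`.
#' @param noise_scale_uV standard deviation of the pink background noise.
#' @param osc_margin_hz oscillator frequencies are drawn uniformly within
#'   `[low + margin, high - margin]` of each band so band energy stays
#'   attributable to its band at 0.5 Hz spectral resolution.
#' @param seed integer seed; fully determines the synthesized signal.
#' @param bands band table.
#' @return a `participant_truth` object.
#' @export
participant_truth <- function(profile, engagement = 0, band_gains = NULL,
                              state_modulation = NULL, coupling = NULL,
                              noise_scale_uV = 2, osc_margin_hz = 1,
                              seed = 1L, bands = default_bands()) {
  stopifnot(inherits(profile, "device_profile"), noise_scale_uV >= 0)
  nb <- nrow(bands); ne <- length(profile$channel_labels)
  if (is.null(band_gains)) {
    defaults <- c(theta = 4, alpha = 6, beta = 2, gamma = 1)
    band_gains <- matrix(defaults[bands$name], nrow = ne, ncol = nb,
                         byrow = TRUE,
                         dimnames = list(profile$channel_labels, bands$name))
  }
  stopifnot(is.matrix(band_gains), nrow(band_gains) == ne,
            ncol(band_gains) == nb, all(is.finite(band_gains)),
            all(band_gains >= 0))
  if (is.null(state_modulation)) state_modulation <- list()
  for (st in c("onset", "offset", "other")) {
    if (is.null(state_modulation[[st]])) {
      state_modulation[[st]] <- matrix(1, ne, nb,
        dimnames = list(profile$channel_labels, bands$name))
    }
  }
  if (!is.null(coupling)) {
    stopifnot(coupling$electrode %in% profile$channel_labels,
              coupling$band %in% bands$name,
              coupling$state %in% c("onset", "offset", "other", "any"),
              is.finite(coupling$coefficient))
  }
  structure(list(engagement = engagement, band_gains = band_gains,
                 state_modulation = state_modulation, coupling = coupling,
                 noise_scale_uV = noise_scale_uV,
                 osc_margin_hz = osc_margin_hz,
                 bands = bands, seed = as.integer(seed)),
            class = "participant_truth")
}

# Effective oscillator amplitude for (electrode, band, state).
truth_amplitude <- function(truth, electrode, band, state) {
  a <- truth$band_gains[electrode, band] *
    truth$state_modulation[[state]][electrode, band]
  cp <- truth$coupling
  if (!is.null(cp) && cp$electrode == electrode && cp$band == band &&
      (cp$state == "any" || cp$state == state)) {
    a <- a * exp(cp$coefficient * truth$engagement)
  }
  a
}

# Task-state segments of a timeline: data.frame(start_s, end_s, state),
# contiguous, covering [0, total_s], adjacent equal states merged.
timeline_states <- function(timeline, total_s) {
  practice <- vapply(timeline$payload,
                     function(p) isTRUE(p$practice), logical(1))
  state <- ifelse(timeline$kind %in% c("display", "probe") & !practice,
                  "onset",
                  ifelse(timeline$kind == "rest", "offset", "other"))
  ev <- data.frame(start_s = timeline$onset_s,
                   end_s = timeline$onset_s + timeline$duration_s,
                   state = state, stringsAsFactors = FALSE)
  # fill gaps (and trailing pad) with "other"
  segs <- list(); t <- 0
  for (i in seq_len(nrow(ev))) {
    if (ev$start_s[i] > t + 1e-9) {
      segs[[length(segs) + 1L]] <- list(t, ev$start_s[i], "other")
    }
    segs[[length(segs) + 1L]] <- list(ev$start_s[i], ev$end_s[i], ev$state[i])
    t <- max(t, ev$end_s[i])
  }
  if (total_s > t + 1e-9) segs[[length(segs) + 1L]] <- list(t, total_s, "other")
  out <- data.frame(start_s = vapply(segs, `[[`, 0, 1L),
                    end_s = vapply(segs, `[[`, 0, 2L),
                    state = vapply(segs, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  # merge adjacent equal states
  keep <- c(TRUE, out$state[-1] != out$state[-nrow(out)])
  idx <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(out, idx), function(d) {
    data.frame(start_s = d$start_s[1], end_s = d$end_s[nrow(d)],
               state = d$state[1], stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged
}

# Pink (1/f^slope in power) noise, unit variance, length n, via FFT shaping.
pink_noise <- function(n, slope = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  ft <- stats::fft(x)
  k <- c(1, seq_len(m - 1L))             # avoid dividing DC by zero
  shape <- 1 / k^(slope / 2)
  shape[1] <- 0
  # keep conjugate symmetry so the inverse transform is real
  half <- floor(m / 2)
  shape[(m - half + 1L):m] <- rev(shape[2:(half + 1L)])
  y <- Re(stats::fft(ft * shape, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  (y - mean(y)) / stats::sd(y)
}

# Zero-phase device filtering, applied in the frequency domain: the signal
# spectrum is multiplied by an amplitude response with zero phase, which is
# what forward-backward filtering does to a stationary signal, at the cost
# of one FFT pair per channel instead of four recursion passes. The
# response is: a 2nd-order Butterworth high-pass at the bandwidth floor;
# 2nd-order Butterworth band-stops at the mains notches (exact zeros at the
# notch frequencies); and a flat passband up to the bandwidth ceiling with
# a raised-cosine anti-alias rolloff reaching zero at the output Nyquist.
# The device's printed bandwidth is read as the flat-passband edge — a
# conventional low-pass with its -3 dB point at the ceiling would attenuate
# upper-gamma content by tens of percent, destroying the in-band spectral
# fidelity the emulator must guarantee, while the rolloff still makes
# decimation alias-free by construction.
device_filter_gain <- function(f, profile, output_rate_hz = NULL) {
  flo <- profile$bandwidth_hz[1]; fhi <- profile$bandwidth_hz[2]
  stop_hz <- min((output_rate_hz %||% profile$output_rate_hz) / 2,
                 profile$internal_rate_hz / 2)
  # each Butterworth term is the single-pass power response, which is the
  # two-pass (zero-phase) amplitude response
  g <- 1 / (1 + (flo / pmax(f, 1e-12))^4)                # HP, order 2
  lp <- numeric(length(f)) + 1
  ramp <- f > fhi & f < stop_hz
  lp[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - fhi) / (stop_hz - fhi)))
  lp[f >= stop_hz] <- 0
  g <- g * lp^2                                          # LP, two-pass
  for (f0 in profile$notch_hz) {
    lo <- f0 - 2; hi <- f0 + 2
    bw <- hi - lo; f02 <- lo * hi
    r <- (bw * f) / (f^2 - f02)
    r[!is.finite(r)] <- Inf
    g <- g / (1 + r^4)                                   # stop, order 2
  }
  g                                                      # amplitude gain
}

apply_device_filters <- function(x, fs, profile) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(m - n))
  f <- c(seq(0, floor(m / 2)), seq(ceiling(m / 2) - 1, 1)) * fs / m
  y <- Re(stats::fft(stats::fft(xp) * device_filter_gain(f, profile),
                     inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Synthesize a recording for a timeline
#'
#' Renders each requested channel as pink background noise plus one
#' oscillator per band. Oscillator amplitude in each task-state segment is
#' `band_gains x state_modulation(state)` (times the engagement coupling
#' where configured); frequency and phase are redrawn uniformly per segment.
#' The signal is generated at the profile's internal rate, filtered to the
#' device bandwidth with zero-phase Butterworth filters, notch-filtered, and
#' decimated to the output rate. Deterministic given `truth$seed`; channel
#' subsets reuse the per-channel seed of the full montage, so synthesizing
#' one channel reproduces that channel of the full synthesis.
#'
#' @param profile a `device_profile`.
#' @param timeline an `event_timeline` (non-empty).
#' @param truth a `participant_truth`.
#' @param channels channels to synthesize (default: full montage).
#' @param start_time_s epoch-seconds timestamp of the first sample.
#' @param max_duration_s refuse timelines longer than this (default 3600 s).
#' @return an unquantized `raw_recording` at `profile$output_rate_hz`.
#' @export
synthesize_recording <- function(profile, timeline, truth,
                                 channels = profile$channel_labels,
                                 start_time_s = 0, max_duration_s = 3600) {
  stopifnot(inherits(profile, "device_profile"),
            inherits(timeline, "event_timeline"),
            inherits(truth, "participant_truth"))
  if (nrow(timeline) == 0L) stop_cs("timeline is empty")
  stopifnot(all(channels %in% profile$channel_labels))
  total_s <- ceiling(timeline_duration(timeline))
  if (total_s > max_duration_s) {
    stop_cs("timeline spans %g s, above the configured maximum of %g s",
            total_s, max_duration_s)
  }
  fs <- profile$internal_rate_hz
  dec <- as.integer(profile$internal_rate_hz / profile$output_rate_hz)
  n_int <- as.integer(round(total_s * fs))
  segs <- timeline_states(timeline, total_s)
  bands <- truth$bands
  chan_seeds <- derive_seeds(truth$seed, length(profile$channel_labels))
  out <- matrix(0, nrow = length(channels),
                ncol = as.integer(round(total_s * profile$output_rate_hz)))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    sig <- with_seed(chan_seeds[match(ch, profile$channel_labels)], {
      x <- if (truth$noise_scale_uV > 0) {
        truth$noise_scale_uV * pink_noise(n_int)
      } else numeric(n_int)
      for (bi in seq_len(nrow(bands))) {
        lo <- bands$low_hz[bi] + truth$osc_margin_hz
        hi <- bands$high_hz[bi] - truth$osc_margin_hz
        if (hi <= lo) { lo <- bands$low_hz[bi]; hi <- bands$high_hz[bi] }
        for (si in seq_len(nrow(segs))) {
          f <- stats::runif(1, lo, hi)
          ph <- stats::runif(1, 0, 2 * pi)
          amp <- truth_amplitude(truth, ch, bands$name[bi], segs$state[si])
          if (amp > 0) {
            i0 <- as.integer(floor(segs$start_s[si] * fs)) + 1L
            i1 <- min(as.integer(ceiling(segs$end_s[si] * fs)), n_int)
            if (i1 >= i0) {
              tt <- (seq(i0, i1) - 1L) / fs
              x[i0:i1] <- x[i0:i1] + amp * sin(2 * pi * f * tt + ph)
            }
          }
        }
      }
      x
    })
    if (any(sig != 0)) sig <- apply_device_filters(sig, fs, profile)
    out[ci, ] <- sig[seq(1L, n_int, by = dec)]
  }
  new_raw_recording(start_time_s, profile$output_rate_hz, channels, out)
}

#' Quantize a recording to the device's ADC grid
#'
#' Rounds every sample to the nearest multiple of `lsb_uV` and clips to the
#' largest representable code within `+/- dynamic_range_uVpp / 2` (the clip
#' value therefore sits within one LSB of the range edge, keeping every
#' output value on the quantization grid). Idempotent.
#'
#' @param recording an unquantized `raw_recording`.
#' @param profile a `device_profile`.
#' @return the quantized `raw_recording`.
#' @export
quantize_recording <- function(recording, profile) {
  stopifnot(inherits(recording, "raw_recording"),
            inherits(profile, "device_profile"))
  code_max <- floor(profile$dynamic_range_uVpp / 2 / profile$lsb_uV)
  code <- round(recording$samples / profile$lsb_uV)
  code[code > code_max] <- code_max
  code[code < -code_max] <- -code_max
  new_raw_recording(recording$start_time_s, recording$rate_hz,
                    recording$channel_labels, code * profile$lsb_uV,
                    quantized = TRUE)
}

contact_levels <- c(black = 0L, red = 1L, orange = 2L, yellow = 3L, green = 4L)

#' Simulate a contact-quality trace
#'
#' Per-electrode contact quality on the standard 5-color scheme (black=0,
#' red=1, orange=2, yellow=3, green=4), simulated as a bounded random walk:
#' at each step each electrode moves one level up or down with probability
#' `drift`, clipped to the valid range. Deterministic given `seed`.
#'
#' @param profile a `device_profile`.
#' @param n_steps number of time steps.
#' @param step_s seconds between steps.
#' @param drift per-step probability of a level change.
#' @param start_level initial level for all electrodes (default 4, green).
#' @param seed integer seed.
#' @return list with `time_s`, integer `levels` (electrodes x steps) and
#'   character `colors` of the same shape.
#' @export
contact_quality_trace <- function(profile, n_steps, step_s = 1, drift = 0.05,
                                  start_level = 4L, seed = 1L) {
  stopifnot(inherits(profile, "device_profile"), n_steps >= 1,
            drift >= 0, drift <= 1, start_level %in% 0:4)
  ne <- length(profile$channel_labels)
  lv <- with_seed(seed, {
    m <- matrix(0L, ne, n_steps,
                dimnames = list(profile$channel_labels, NULL))
    cur <- rep(as.integer(start_level), ne)
    for (s in seq_len(n_steps)) {
      move <- stats::runif(ne) < drift
      dir <- sample(c(-1L, 1L), ne, replace = TRUE)
      cur <- pmin(4L, pmax(0L, cur + ifelse(move, dir, 0L)))
      m[, s] <- cur
    }
    m
  })
  cols <- matrix(names(contact_levels)[lv + 1L], nrow = ne,
                 dimnames = dimnames(lv))
  list(time_s = (seq_len(n_steps) - 1L) * step_s, levels = lv, colors = cols)
}

#' Split a recording into timestamped stream chunks
#'
#' Emulates the live-stream contract of a wireless headset: the recording is
#' cut into consecutive chunks of `chunk_s` seconds (the last chunk may be
#' shorter), each carrying its own start timestamp. Concatenating the chunks
#' reproduces the recording exactly.
#'
#' @param recording a `raw_recording`.
#' @param chunk_s chunk length in seconds (> 0).
#' @return list of chunks, each a list with `start_time_s` and `samples`.
#' @export
stream_chunks <- function(recording, chunk_s) {
  stopifnot(inherits(recording, "raw_recording"), chunk_s > 0)
  per <- max(1L, as.integer(round(chunk_s * recording$rate_hz)))
  n <- ncol(recording$samples)
  starts <- seq(1L, n, by = per)
  lapply(starts, function(s) {
    e <- min(s + per - 1L, n)
    list(start_time_s = recording$start_time_s + (s - 1L) / recording$rate_hz,
         samples = recording$samples[, s:e, drop = FALSE])
  })
}

#' Inject a large-amplitude transient into a recording
#'
#' Adds a square transient of given amplitude to one channel over
#' `[t_start_s, t_start_s + duration_s)` (relative to the recording start).
#' Exists to exercise artifact cleaning with a known ground-truth location.
#'
#' @param recording a `raw_recording`.
#' @param channel channel label.
#' @param t_start_s,duration_s transient window, seconds from recording start.
#' @param amplitude_uV transient amplitude in uV.
#' @return the modified `raw_recording`.
#' @export
inject_transient <- function(recording, channel, t_start_s, duration_s,
                             amplitude_uV = 500) {
  stopifnot(channel %in% recording$channel_labels)
  i0 <- as.integer(floor(t_start_s * recording$rate_hz)) + 1L
  i1 <- min(as.integer(ceiling((t_start_s + duration_s) * recording$rate_hz)),
            ncol(recording$samples))
  stopifnot(i0 >= 1L, i1 >= i0)
  recording$samples[channel, i0:i1] <-
    recording$samples[channel, i0:i1] + amplitude_uV
  recording
}
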