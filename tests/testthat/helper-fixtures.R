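# Shared fixtures: all built in code at test time.

# A pure-tone recording: one sinusoid per channel at given frequencies and
# amplitudes, no noise, sampled at `rate_hz` for `duration_s`.
tone_recording <- function(freqs_hz, amps, rate_hz = 128, duration_s = 10,
                           labels = paste0("CH", seq_along(freqs_hz))) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  samples <- t(mapply(function(f, a) a * sin(2 * pi * f * t), freqs_hz, amps))
  cogstream:::new_raw_recording(0, rate_hz, labels, samples)
}

# Truth with a single oscillator (one electrode, one band), zero noise.
single_tone_truth <- function(profile, electrode, band, amplitude,
                              seed = 1L, ...) {
  gains <- matrix(0, length(profile$channel_labels),
                  nrow(default_bands()),
                  dimnames = list(profile$channel_labels,
                                  default_bands()$name))
  gains[electrode, band] <- amplitude
  participant_truth(profile, band_gains = gains, noise_scale_uV = 0,
                    seed = seed, ...)
}

# Small, fast n-Back spec for pipeline tests.
quick_nback <- function(total = 12, seed = 1L, practice = 0L) {
  nback_spec(n = 2, total_trials = total, practice_trials = practice,
             rest_duration_s = 10, seed = seed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
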