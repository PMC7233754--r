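# Synthetic headset stream: spectral fidelity, filters, quantization,
# contact quality, chunked streaming.

test_that("a pure in-band oscillator lands its power in its own band", {
  p <- epoc_default_profile()
  tl <- compose_eyes(eyes_spec(2, interval_s = 15))
  bands <- default_bands()
  for (bi in seq_len(nrow(bands))) {
    A <- 2.5
    truth <- single_tone_truth(p, "P7", bands$name[bi], A, seed = 20 + bi)
    rec <- synthesize_recording(p, tl, truth, channels = "P7")
    psd <- welch_psd(rec$samples, rec$rate_hz)
    bp <- vapply(bands$name, function(b) band_power(psd, b)[[1]], numeric(1))
    own <- bp[bands$name[bi]]
    # Parseval: integrated band power within 10% of A^2/2
    expect_rel_equal(own, A^2 / 2, 0.1)
    # >= 100x the power found in any other band
    expect_gt(own, 100 * max(bp[bands$name != bands$name[bi]]))
  }
})

test_that("zero gains and zero noise give an all-zero recording", {
  p <- recovery_profile()
  gains <- matrix(0, 14, 4, dimnames = list(p$channel_labels,
                                            default_bands()$name))
  truth <- participant_truth(p, band_gains = gains, noise_scale_uV = 0)
  rec <- synthesize_recording(p, compose_eyes(eyes_spec(1, interval_s = 4)),
                              truth, channels = c("P7", "F7"))
  expect_true(all(rec$samples == 0))
})

test_that("synthesis is deterministic and channel-subset consistent", {
  p <- recovery_profile()
  tl <- compose_eyes(eyes_spec(2, interval_s = 5))
  truth <- participant_truth(p, seed = 77)
  r1 <- synthesize_recording(p, tl, truth)
  r2 <- synthesize_recording(p, tl, truth)
  expect_identical(r1$samples, r2$samples)
  # synthesizing only P7 reproduces the P7 row of the full montage
  rp <- synthesize_recording(p, tl, truth, channels = "P7")
  expect_identical(rp$samples["P7", ], r1$samples["P7", ])
})

test_that("state modulation changes oscillator amplitude between states", {
  p <- recovery_profile()
  spec <- quick_nback(12, seed = 8)
  tl <- build_timeline(compose_nback(spec), spec)
  sm <- list(onset = NULL, offset = NULL, other = NULL)
  gains <- matrix(0, 14, 4, dimnames = list(p$channel_labels,
                                            default_bands()$name))
  gains["P7", "theta"] <- 3
  mod1 <- matrix(1, 14, 4, dimnames = dimnames(gains))
  mod2 <- mod1; mod2["P7", "theta"] <- 0.25
  truth <- participant_truth(p, band_gains = gains,
                             state_modulation = list(onset = mod1,
                                                     offset = mod2),
                             noise_scale_uV = 0, seed = 5)
  rec <- synthesize_recording(p, tl, truth, channels = "P7")
  session <- cogstream:::new_session("s", "p", task_spec("nback", spec),
                                     compose_nback(spec), tl, rec, NULL, 0,
                                     p$name)
  on_ep <- extract_epochs(session, "onset")
  off_ep <- extract_epochs(session, "offset")
  pw <- function(ep) band_power(welch_psd(ep$samples, ep$rate_hz), "theta")[[1]]
  expect_rel_equal(pw(on_ep[[1]]), 3^2 / 2, 0.15)
  expect_rel_equal(pw(off_ep[[1]]), (3 * 0.25)^2 / 2, 0.15)
})

test_that("a mains-frequency tone is notched out by >= 20 dB", {
  p <- epoc_default_profile()
  fs <- p$internal_rate_hz
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  for (f0 in p$notch_hz) {
    x <- sin(2 * pi * f0 * t)
    y <- cogstream:::apply_device_filters(x, fs, p)
    atten_db <- 10 * log10(mean(x^2) / max(mean(y^2), 1e-300))
    expect_gt(atten_db, 20)
  }
  # passband content passes essentially unattenuated
  x10 <- sin(2 * pi * 10 * t)
  y10 <- cogstream:::apply_device_filters(x10, fs, p)
  expect_rel_equal(mean(y10^2), mean(x10^2), 0.02)
})

test_that("pink background noise has a falling spectrum", {
  p <- recovery_profile()
  truth <- participant_truth(p, band_gains = matrix(
    0, 14, 4, dimnames = list(p$channel_labels, default_bands()$name)),
    noise_scale_uV = 2, seed = 31)
  rec <- synthesize_recording(p, compose_eyes(eyes_spec(2, interval_s = 20)),
                              truth, channels = "O1")
  psd <- welch_psd(rec$samples, rec$rate_hz, window_s = 4)
  lowband <- band_power(psd, list(low_hz = 2, high_hz = 8))[[1]]
  highband <- band_power(psd, list(low_hz = 26, high_hz = 32))[[1]]
  expect_gt(lowband, 3 * highband)
})

test_that("quantization rounds to the LSB grid, clips, and is idempotent", {
  p <- epoc_default_profile()
  rec <- cogstream:::new_raw_recording(
    0, 128, "P7", matrix(c(1.02, 0.2, 10000, -10000, 0.26), nrow = 1))
  q <- quantize_recording(rec, p)
  expect_true(q$quantized)
  v <- unname(q$samples[1, ])
  expect_equal(v[1], 1.02)                      # exactly 2 LSB
  expect_equal(v[2], 0)                         # rounds down to 0
  # out-of-range samples clip to within one LSB of +/- range/2
  expect_lte(abs(v[3] - 4200), p$lsb_uV)
  expect_lte(abs(v[4] + 4200), p$lsb_uV)
  expect_true(all(abs(q$samples) <= 4200))
  expect_equal(v[5], 0.51)                      # rounds up to 1 LSB
  ongrid <- q$samples / p$lsb_uV
  expect_true(all(abs(ongrid - round(ongrid)) < 1e-9))
  q2 <- quantize_recording(q, p)
  expect_identical(q2$samples, q$samples)
})

test_that("contact quality is a bounded deterministic random walk", {
  p <- epoc_default_profile()
  frozen <- contact_quality_trace(p, 50, drift = 0, seed = 1)
  expect_true(all(frozen$levels == 4L))
  tr1 <- contact_quality_trace(p, 200, drift = 0.3, seed = 9)
  tr2 <- contact_quality_trace(p, 200, drift = 0.3, seed = 9)
  expect_identical(tr1$levels, tr2$levels)
  expect_true(all(tr1$levels %in% 0:4))
  expect_true(any(tr1$levels != 4L))            # the walk actually moves
  expect_setequal(unique(as.vector(tr1$colors)),
                  names(cogstream:::contact_levels)[sort(unique(as.vector(tr1$levels))) + 1L])
})

test_that("stream chunks carry timestamps and reassemble exactly", {
  p <- recovery_profile()
  truth <- participant_truth(p, seed = 3)
  rec <- synthesize_recording(p, compose_eyes(eyes_spec(2, interval_s = 5)),
                              truth, channels = c("P7", "O2"))
  chunks <- stream_chunks(rec, 1)
  expect_length(chunks, 10L)
  expect_true(all(vapply(chunks, function(c) ncol(c$samples), integer(1)) == 128L))
  expect_equal(vapply(chunks, function(c) c$start_time_s, numeric(1)),
               seq(0, 9))
  expect_identical(do.call(cbind, lapply(chunks, `[[`, "samples")),
                   rec$samples)
  whole <- stream_chunks(rec, 60)
  expect_length(whole, 1L)
  expect_identical(whole[[1]]$samples, rec$samples)
})

test_that("over-long timelines are refused", {
  p <- recovery_profile()
  truth <- participant_truth(p)
  tl <- compose_eyes(eyes_spec(10, interval_s = 30))
  expect_error(synthesize_recording(p, tl, truth, channels = "P7",
                                    max_duration_s = 100),
               "maximum")
})

test_that("analytic filter responses match a reference digital filter design", {
  # independent route: Butterworth filters designed with signal::butter,
  # magnitude evaluated with freqz; at fs = 2048 Hz the bilinear warp is
  # negligible below 100 Hz, so the emulator's analytic responses must
  # agree closely
  p <- epoc_default_profile()
  fs <- p$internal_rate_hz
  f <- c(1, 6, 10, 25, 40)      # below the 43 Hz rolloff onset
  mag <- function(filt) abs(signal::freqz(filt, n = f, Fs = fs)$h)
  hp <- mag(signal::butter(2, p$bandwidth_hz[1] / (fs / 2), type = "high"))
  bs50 <- mag(signal::butter(2, c(48, 52) / (fs / 2), type = "stop"))
  bs60 <- mag(signal::butter(2, c(58, 62) / (fs / 2), type = "stop"))
  # zero-phase (forward-backward) response = squared single-pass magnitude
  ref <- (hp * bs50 * bs60)^2
  got <- cogstream:::device_filter_gain(f, p)
  expect_equal(got, ref, tolerance = 1e-3)
  # deep notches at the mains frequencies (> 100 dB), silence at/beyond
  # the output Nyquist
  expect_lt(max(cogstream:::device_filter_gain(c(50, 60), p)), 1e-5)
  expect_identical(cogstream:::device_filter_gain(c(64, 80), p), c(0, 0))
})
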