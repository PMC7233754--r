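# Cleaning, epoching, band-power tables, behavioral scoring, cohort joins.

make_session <- function(total = 12, seed = 2, channels = "P7",
                         responder = responder_model(seed = 7),
                         profile = recovery_profile()) {
  spec <- quick_nback(total, seed = seed)
  run_session(participant("p01"), spec, profile,
              participant_truth(profile, seed = seed), responder = responder,
              channels = channels)
}

test_that("clean synthetic recordings produce an empty mask", {
  sess <- make_session()
  mask <- clean_recording(sess$recording)
  expect_false(any(mask))
  expect_equal(attr(mask, "masked_fraction"), 0)
})

test_that("an injected transient masks exactly the windows covering it", {
  sess <- make_session(channels = c("P7", "F7"))
  rec <- inject_transient(sess$recording, "P7", t_start_s = 10.2,
                          duration_s = 0.5, amplitude_uV = 500)
  mask <- clean_recording(rec, amplitude_threshold_uV = 100, window_s = 1)
  # transient spans 10.2-10.7 s -> windows 11 and (boundary sample) 12
  hit <- which(mask["P7", ])
  expect_true(all(hit %in% c(11L, 12L)))
  expect_true(11L %in% hit)
  expect_false(any(mask["F7", ]))
})

test_that("flatline channels are masked whole", {
  sess <- make_session(channels = c("P7", "F7"))
  rec <- sess$recording
  rec$samples["F7", ] <- 0
  mask <- clean_recording(rec)
  expect_true(all(mask["F7", ]))
  expect_false(any(mask["P7", ]))
})

test_that("epoch extraction follows the trial/rest structure", {
  p <- recovery_profile()
  spec <- nback_spec(2, 36, practice_trials = 7, rest_duration_s = 10,
                     seed = 3)
  sess <- run_session(participant("p01"), spec, p,
                      participant_truth(p, seed = 3), channels = "P7")
  on_ep <- extract_epochs(sess, "onset")
  off_ep <- extract_epochs(sess, "offset")
  expect_length(on_ep, 36L)
  expect_length(off_ep, 3L)
  # onset epoch duration = (displays + probe) slots
  types <- vapply(sess$sequence, function(t) t$trial_type, integer(1))
  durs <- vapply(on_ep, function(e) ncol(e$samples) / e$rate_hz, numeric(1))
  expect_equal(durs[order(vapply(on_ep, function(e) e$trial_index, 1L))],
               (types + 1) * 2)
  n3 <- which(types == 3)[1]   # an n+1 trial: 3 displays + probe = 8 s
  expect_equal(durs[vapply(on_ep, function(e) e$trial_index, 1L) == n3 - 1L], 8)
  # practice trials contribute no epochs
  expect_true(all(vapply(on_ep, function(e) e$trial_index, 1L) %in% 0:35))
})

test_that("epochs overlapping masked windows are dropped", {
  sess <- make_session(total = 12)
  rec <- inject_transient(sess$recording, "P7",
                          t_start_s = sess$timeline$onset_s[1] + 0.5,
                          duration_s = 0.2, amplitude_uV = 800)
  mask <- clean_recording(rec)
  kept <- extract_epochs(sess, "onset", mask = mask)
  expect_length(kept, 11L)
  expect_false(0L %in% vapply(kept, function(e) e$trial_index, 1L))
  # masking everything warns about an empty result
  rec$samples[] <- 0
  allmask <- clean_recording(rec)
  expect_warning(extract_epochs(sess, "onset", mask = allmask),
                 "no onset epochs")
})

test_that("band-power rows average epoch powers and respect known truth", {
  p <- recovery_profile()
  spec <- quick_nback(12, seed = 9)
  sess <- run_session(participant("p01"), spec, p,
                      single_tone_truth(p, "P7", "alpha", 3, seed = 9),
                      channels = "P7", quantize = FALSE)
  bp <- session_band_power(sess, states = "onset")
  expect_equal(nrow(bp), 4L)             # one electrode x four bands
  expect_equal(unique(bp$n_epochs), 12L)
  alpha <- bp$mean_power_uV2[bp$band == "alpha"]
  expect_rel_equal(alpha, 3^2 / 2, 0.1)
  expect_lt(max(bp$mean_power_uV2[bp$band != "alpha"]), 0.01 * alpha)
  # the table's mean is the unweighted mean of the per-epoch band powers
  per_epoch <- vapply(extract_epochs(sess, "onset"), function(e) {
    band_power(welch_psd(e$samples, e$rate_hz), "alpha")[[1]]
  }, numeric(1))
  expect_equal(alpha, mean(per_epoch), tolerance = 1e-12)
})

test_that("relative band powers sum to one across the band set", {
  sess <- make_session()
  bp <- session_band_power(sess, states = "onset", relative = TRUE)
  expect_equal(sum(bp$mean_power_uV2), 1, tolerance = 1e-9)
})

test_that("behavioral metrics follow signal-detection counting", {
  sess <- make_session(total = 36, seed = 11)
  matched <- vapply(sess$sequence, function(t) t$matched, logical(1))
  # force a known response pattern: press on 10 matched, 3 unmatched
  rs <- sess$responses
  rs$pressed <- FALSE
  rs$reaction_time_s <- NA_real_
  midx <- which(matched[rs$trial_index + 1L])
  uidx <- which(!matched[rs$trial_index + 1L])
  rs$pressed[c(midx[1:10], uidx[1:3])] <- TRUE
  rs$reaction_time_s[rs$pressed] <- 0.6
  sess$responses <- rs
  bm <- behavioral_metrics(sess)
  expect_equal(bm$hits, 10L)
  expect_equal(bm$misses, 8L)
  expect_equal(bm$false_alarms, 3L)
  expect_equal(bm$correct_rejections, 15L)
  expect_equal(bm$accuracy, 25 / 36)
  expect_equal(bm$hits + bm$misses, sum(matched))
  expect_equal(bm$false_alarms + bm$correct_rejections, sum(!matched))
  expect_equal(bm$mean_rt_hits_s, 0.6)
})

test_that("a perfect responder scores accuracy 1, a mute one 0.5", {
  perfect <- make_session(total = 36, seed = 12,
                          responder = responder_model(hit_rate_base = 1,
                                                      false_alarm_rate = 0,
                                                      seed = 1))
  bm <- behavioral_metrics(perfect)
  expect_equal(bm$accuracy, 1)
  expect_equal(bm$hits, 18L)
  expect_equal(bm$correct_rejections, 18L)
  mute <- make_session(total = 36, seed = 12,
                       responder = responder_model(hit_rate_base = 0,
                                                   false_alarm_rate = 0,
                                                   seed = 1))
  bm0 <- behavioral_metrics(mute)
  expect_equal(bm0$accuracy, 0.5)
  expect_true(is.na(bm0$mean_rt_hits_s))
})

test_that("count identities hold across randomized responder simulations", {
  for (seed in 1:6) {
    sess <- make_session(total = 24, seed = seed,
                         responder = responder_model(
                           hit_rate_base = runif(1, 0.3, 0.95),
                           false_alarm_rate = runif(1, 0, 0.4),
                           seed = seed + 50))
    bm <- behavioral_metrics(sess)
    expect_equal(bm$hits + bm$misses, 12L)
    expect_equal(bm$false_alarms + bm$correct_rejections, 12L)
    expect_equal(bm$accuracy,
                 (bm$hits + bm$correct_rejections) / 24)
  }
})

test_that("cohort correlation joins pairwise and reports n actually used", {
  bp <- data.frame(participant_id = sprintf("p%02d", 1:6),
                   session_id = "s", state = "onset", electrode = "P7",
                   band = "theta",
                   mean_power_uV2 = c(1, 2, 3, 4, 5, 6), n_epochs = 5L)
  beh <- data.frame(participant_id = sprintf("p%02d", 1:6),
                    mean_rt_hits_s = c(0.5, 0.6, 0.65, 0.7, NA, 0.9),
                    accuracy = c(0.7, 0.75, 0.8, 0.85, 0.9, 0.95))
  out <- correlate_cohort(bp, beh, statistics = "spearman")
  rt_row <- out[out$metric == "mean_rt_hits_s", ]
  expect_equal(rt_row$n, 5L)              # the NA participant is dropped
  expect_equal(rt_row$estimate, 1)
  acc_row <- out[out$metric == "accuracy", ]
  expect_equal(acc_row$n, 6L)
  # under 3 complete pairs the row is skipped with a warning
  beh2 <- beh; beh2$mean_rt_hits_s[1:4] <- NA
  expect_warning(out2 <- correlate_cohort(bp, beh2, metrics = "mean_rt_hits_s",
                                          statistics = "spearman"),
                 "complete pairs")
  expect_equal(nrow(out2), 0L)
  # optional multiplicity adjustment adds a BH column
  adj <- correlate_cohort(bp, beh, adjust = TRUE)
  expect_true("p_adjusted" %in% names(adj))
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-12))
})
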