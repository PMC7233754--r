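# Synthetic cohorts with known brain-behavior coupling.
#
# The generator plants a target population rank correlation between
# theta-band EEG power in the working-memory onset state and mean hit
# reaction time, then the analysis pipeline is asked to recover it. Two
# correlated standard-normal latents drive the two sides: an EEG engagement
# trait e (multiplying the coupled band amplitude by exp(coef * e)) and a
# behavioral latent b (shifting the median RT linearly). For bivariate
# normal latents with Pearson correlation r the population Spearman
# correlation of any monotone transforms is (6/pi) * asin(r/2), so the
# generator inverts that map: r = 2 * sin(pi * rho_s / 6). Both measured
# quantities are kept high signal-to-noise so measurement attenuation stays
# small.

#' Latent-normal correlation for a target Spearman correlation
#'
#' Inverse of the bivariate-normal rank-correlation identity
#' `rho_s = (6/pi) asin(r/2)`.
#'
#' @param rho_s target population Spearman correlation in (-1, 1).
#' @return the latent Pearson correlation `r`.
#' @export
latent_correlation <- function(rho_s) {
  stopifnot(abs(rho_s) < 1 + 1e-12)
  2 * sin(pi * rho_s / 6)
}

#' Simulate a cohort of n-Back sessions with planted coupling
#'
#' Draws per-participant latents `(e, b)` from a standard bivariate normal
#' with correlation `latent_correlation(rho)`, builds a ground truth whose
#' coupled band amplitude scales as `exp(coupling_coefficient * e)` in the
#' coupled state, simulates the behavioral responder at engagement `b`, and
#' runs one session per participant.
#'
#' @param n_participants cohort size.
#' @param rho target population Spearman correlation between coupled-band
#'   power and mean hit RT (0 for a null cohort).
#' @param seed master seed for the whole cohort.
#' @param profile device profile for the emulated headset.
#' @param task an `nback_spec` (its `seed` is re-derived per participant).
#' @param electrode,band,state the coupled signal selection.
#' @param coupling_coefficient log-amplitude shift per unit engagement.
#' @param noise_scale_uV pink-noise scale passed to the truth.
#' @param responder baseline `responder_model`; its RT slope ties behavior
#'   to the latent `b` and its seed is re-derived per participant.
#' @param channels channels to synthesize (defaults to just the coupled
#'   electrode; pass `profile$channel_labels` for full-montage sessions).
#' @return list with `sessions`, the latent draws (`engagement`,
#'   `behavioral`), and the generating parameters.
#' @export
simulate_cohort <- function(n_participants = 15, rho = 0.6, seed = 1L,
                            profile = epoc_default_profile(),
                            task = nback_spec(n = 2, total_trials = 24,
                                              practice_trials = 0,
                                              rest_duration_s = 20),
                            electrode = "P7", band = "theta",
                            state = "onset", coupling_coefficient = 0.4,
                            noise_scale_uV = 2,
                            responder = responder_model(
                              engagement_rt_slope = 0.15),
                            channels = electrode) {
  stopifnot(inherits(task, "nback_spec"), electrode %in% profile$channel_labels)
  r <- latent_correlation(rho)
  seeds <- derive_seeds(seed, 3L * n_participants + 1L)
  latents <- with_seed(seeds[1L], {
    e <- stats::rnorm(n_participants)
    z <- stats::rnorm(n_participants)
    list(e = e, b = r * e + sqrt(1 - r^2) * z)
  })
  sessions <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("sim%02d", i)
    truth <- participant_truth(
      profile, engagement = latents$e[i],
      coupling = list(electrode = electrode, band = band, state = state,
                      coefficient = coupling_coefficient),
      noise_scale_uV = noise_scale_uV, seed = seeds[3L * i - 1L])
    task_i <- task
    task_i$seed <- seeds[3L * i]
    resp_i <- responder
    resp_i$seed <- seeds[3L * i + 1L]
    sessions[[i]] <- run_session(participant(pid), task_i, profile, truth,
                                 responder = resp_i,
                                 behavioral_engagement = latents$b[i],
                                 session_id = pid, channels = channels)
  }
  list(sessions = sessions, engagement = latents$e, behavioral = latents$b,
       rho = rho, electrode = electrode, band = band, state = state)
}

#' Recover the planted cohort correlation
#'
#' Runs the analysis pipeline over the cohort's sessions — band-power table
#' at the coupled selection, behavioral metrics, cohort correlation — and
#' returns the recovered coefficient row.
#'
#' @param cohort output of [simulate_cohort()].
#' @param metric behavioral metric to correlate (default mean hit RT).
#' @param statistic `"spearman"` or `"pearson"`.
#' @return one-row data.frame from [correlate_cohort()].
#' @export
recover_cohort_correlation <- function(cohort, metric = "mean_rt_hits_s",
                                       statistic = "spearman") {
  bp <- cohort_band_power(cohort$sessions, electrodes = cohort$electrode,
                          states = cohort$state)
  beh <- do.call(rbind, lapply(cohort$sessions, behavioral_metrics))
  correlate_cohort(bp, beh, electrodes = cohort$electrode,
                   bands = cohort$band, states = cohort$state,
                   metrics = metric, statistics = statistic)
}

#' Replicate-cohort parameter-recovery study
#'
#' Simulates `n_replicates` independent cohorts with a planted population
#' Spearman correlation and recovers each one through the full pipeline.
#' The default device profile is the standard montage run at a 256 Hz
#' internal rate (all synthesized content lies below 43 Hz, so the reduced
#' internal rate is spectrally equivalent and keeps hundreds of replicate
#' cohorts desk-scale).
#'
#' @param n_replicates number of replicate cohorts.
#' @param n_participants cohort size per replicate.
#' @param rho planted population Spearman correlation.
#' @param seed master seed; replicate seeds are derived from it.
#' @param profile device profile (see above for the default).
#' @param ... further arguments passed to [simulate_cohort()].
#' @return list with per-replicate estimates (`rho_hat`), `mean_rho`,
#'   `sign_rate` (fraction of replicates recovering the planted sign;
#'   `NA` when `rho = 0`), and the study parameters.
#' @export
recovery_study <- function(n_replicates = 200, n_participants = 15,
                           rho = 0.6, seed = 1L,
                           profile = recovery_profile(), ...) {
  seeds <- derive_seeds(seed, n_replicates)
  rho_hat <- numeric(n_replicates)
  for (k in seq_len(n_replicates)) {
    cohort <- simulate_cohort(n_participants = n_participants, rho = rho,
                              seed = seeds[k], profile = profile, ...)
    rho_hat[k] <- recover_cohort_correlation(cohort)$estimate
  }
  list(rho_hat = rho_hat, mean_rho = mean(rho_hat),
       sign_rate = if (rho != 0) mean(sign(rho_hat) == sign(rho)) else NA_real_,
       rho = rho, n_replicates = n_replicates,
       n_participants = n_participants)
}

#' Standard montage profile at a reduced internal rate
#'
#' Identical to [epoc_default_profile()] except the internal ADC rate is
#' 256 Hz (2x the 128 Hz output). The emulator synthesizes no content above
#' the 43 Hz analog bandwidth, so recordings are spectrally equivalent to
#' the 2048 Hz profile while an order of magnitude cheaper to generate —
#' the profile used for large replicate studies.
#'
#' @return a `device_profile`.
#' @export
recovery_profile <- function() {
  p <- epoc_default_profile()
  p$name <- "EPOC-sim256"
  p$internal_rate_hz <- 256
  validate_device_profile(p)
  p
}
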