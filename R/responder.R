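# Simulated behavioral responder.
#
# Keypresses on n-Back probes follow a signal-detection scheme: matched
# probes are pressed with a logistic-transformed hit probability, unmatched
# probes with the false-alarm rate. Reaction times are lognormal around a
# median that shifts linearly with the participant's engagement, truncated
# to the response window.

#' Parameterize a simulated responder
#'
#' @param hit_rate_base baseline probability of pressing on a matched probe
#'   (at engagement 0).
#' @param false_alarm_rate probability of pressing on an unmatched probe.
#' @param rt_median_s median reaction time in seconds (at engagement 0).
#' @param rt_sigma lognormal sigma of the reaction-time distribution
#'   (log scale).
#' @param engagement_rt_slope seconds of median-RT shift per unit engagement.
#' @param engagement_acc_slope log-odds shift of the hit probability per
#'   unit engagement.
#' @param seed integer seed.
#' @return a `responder_model` object.
#' @export
responder_model <- function(hit_rate_base = 0.8, false_alarm_rate = 0.1,
                            rt_median_s = 0.7, rt_sigma = 0.15,
                            engagement_rt_slope = 0,
                            engagement_acc_slope = 0, seed = 1L) {
  stopifnot(hit_rate_base >= 0, hit_rate_base <= 1,
            false_alarm_rate >= 0, false_alarm_rate <= 1,
            rt_median_s > 0, rt_sigma > 0)
  structure(list(hit_rate_base = hit_rate_base,
                 false_alarm_rate = false_alarm_rate,
                 rt_median_s = rt_median_s, rt_sigma = rt_sigma,
                 engagement_rt_slope = engagement_rt_slope,
                 engagement_acc_slope = engagement_acc_slope,
                 seed = as.integer(seed)),
            class = "responder_model")
}

rt_floor_s <- 0.05

# One truncated-lognormal RT draw via inverse-CDF so truncation stays
# deterministic under the seed.
draw_rt <- function(median_s, sigma, window_s) {
  meanlog <- log(median_s)
  u <- stats::runif(1) * stats::plnorm(window_s, meanlog, sigma)
  max(stats::qlnorm(u, meanlog, sigma), 1e-4)
}

#' Simulate keypress responses for an n-Back run
#'
#' For each non-practice probe in the timeline: a matched probe is pressed
#' with probability `plogis(qlogis(hit_rate_base) +
#' engagement_acc_slope * engagement)`, an unmatched probe with probability
#' `false_alarm_rate`. Pressed probes get a reaction time drawn lognormal
#' with median `rt_median_s + engagement_rt_slope * engagement` and sigma
#' `rt_sigma`, truncated to the response window. Deterministic given
#' `model$seed`.
#'
#' @param sequence a `trial_sequence` from [compose_nback()].
#' @param timeline the matching `event_timeline` from [build_timeline()].
#' @param model a `responder_model`.
#' @param engagement the participant's behavioral engagement value.
#' @param start_time_s epoch-seconds origin for response timestamps.
#' @return data.frame with one row per non-practice probe: `trial_index`,
#'   `pressed`, `reaction_time_s` (`NA` when not pressed), `timestamp_s`.
#' @export
simulate_responses <- function(sequence, timeline, model, engagement = 0,
                               start_time_s = 0) {
  stopifnot(inherits(sequence, "trial_sequence"),
            inherits(timeline, "event_timeline"),
            inherits(model, "responder_model"))
  probes <- which(timeline$kind == "probe" & !is.na(timeline$trial_index))
  if (length(probes) != length(sequence)) {
    stop_cs("timeline has %d main-block probes but sequence has %d trials",
            length(probes), length(sequence))
  }
  windows <- vapply(timeline$payload[probes],
                    function(p) p$response_window_s, numeric(1))
  if (any(windows < rt_floor_s)) {
    stop_cs("response window (%g s) shorter than the minimum RT floor (%g s)",
            min(windows), rt_floor_s)
  }
  median_s <- model$rt_median_s + model$engagement_rt_slope * engagement
  if (median_s <= 0) {
    stop_cs("engagement shifts median RT to %g s; must stay positive", median_s)
  }
  p_hit <- stats::plogis(stats::qlogis(min(max(model$hit_rate_base, 1e-12),
                                           1 - 1e-12)) +
                         model$engagement_acc_slope * engagement)
  if (model$hit_rate_base == 0) p_hit <- 0
  if (model$hit_rate_base == 1) p_hit <- 1
  with_seed(model$seed, {
    n <- length(probes)
    pressed <- logical(n); rt <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ti <- timeline$trial_index[probes[i]]
      matched <- sequence[[ti + 1L]]$matched
      p <- if (matched) p_hit else model$false_alarm_rate
      press <- stats::runif(1) < p
      if (press) rt[i] <- draw_rt(median_s, model$rt_sigma, windows[i])
      pressed[i] <- press
    }
    data.frame(trial_index = timeline$trial_index[probes],
               pressed = pressed, reaction_time_s = rt,
               timestamp_s = start_time_s + timeline$onset_s[probes] +
                 ifelse(pressed, rt, NA_real_))
  })
}
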