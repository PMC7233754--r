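# Session analysis: artifact masking, state epoching, band-power tables,
# signal-detection behavioral metrics and cohort correlations.

#' Mask artifact-contaminated windows of a recording
#'
#' Scans fixed-length windows per channel and masks any window whose peak
#' absolute amplitude exceeds `amplitude_threshold_uV` or whose variance is
#' zero (flatline, e.g. a railed or disconnected electrode). Epochs that
#' overlap a masked window on any analyzed channel are excluded downstream.
#'
#' @param recording a `raw_recording`.
#' @param amplitude_threshold_uV rejection threshold in uV (default 100).
#' @param window_s mask window length in seconds (default 1).
#' @return a `rejection_mask`: logical channels x windows matrix (TRUE =
#'   rejected) with the window length and masked fraction as attributes.
#' @export
clean_recording <- function(recording, amplitude_threshold_uV = 100,
                            window_s = 1) {
  stopifnot(inherits(recording, "raw_recording"),
            amplitude_threshold_uV > 0, window_s > 0)
  per <- max(1L, as.integer(round(window_s * recording$rate_hz)))
  n <- ncol(recording$samples)
  nwin <- as.integer(ceiling(n / per))
  mask <- matrix(FALSE, nrow(recording$samples), nwin,
                 dimnames = list(recording$channel_labels, NULL))
  for (w in seq_len(nwin)) {
    cols <- ((w - 1L) * per + 1L):min(w * per, n)
    seg <- recording$samples[, cols, drop = FALSE]
    peak <- apply(abs(seg), 1L, max)
    flat <- apply(seg, 1L, stats::var) == 0
    mask[, w] <- peak > amplitude_threshold_uV | flat
  }
  structure(mask, class = c("rejection_mask", "matrix", "array"),
            window_s = window_s, rate_hz = recording$rate_hz,
            masked_fraction = mean(mask))
}

epoch_hits_mask <- function(mask, i0, i1) {
  # does sample range [i0, i1] (0-based) overlap any masked window?
  per <- attr(mask, "window_s") * attr(mask, "rate_hz")
  w0 <- floor(i0 / per) + 1L
  w1 <- min(floor(i1 / per) + 1L, ncol(mask))
  any(mask[, w0:w1, drop = FALSE])
}

#' Extract state-locked epochs from a session
#'
#' Working-memory `"onset"` epochs span each non-practice trial from its
#' first display onset to its probe offset; `"offset"` epochs span each rest
#' event. Boundaries are converted to sample indices on the session clock;
#' epochs overlapping a masked window (when a rejection mask is given) are
#' dropped. Practice trials contribute no epochs.
#'
#' @param session a `cog_session`.
#' @param state `"onset"` or `"offset"`.
#' @param mask optional `rejection_mask` from [clean_recording()].
#' @return list of epochs (`samples` channels x time, `rate_hz`, `t0_s`,
#'   `state`, `trial_index`); empty with a warning if none survive.
#' @export
extract_epochs <- function(session, state = c("onset", "offset"),
                           mask = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(session, "cog_session"))
  tl <- session$timeline
  rec <- session$recording
  spans <- if (state == "onset") {
    idx <- which(!is.na(tl$trial_index) & tl$kind %in% c("display", "probe"))
    sp <- split(idx, tl$trial_index[idx])
    lapply(sp, function(ii) {
      c(min(tl$onset_s[ii]), max(tl$onset_s[ii] + tl$duration_s[ii]),
        tl$trial_index[ii[1]])
    })
  } else {
    idx <- which(tl$kind == "rest")
    lapply(idx, function(i) {
      c(tl$onset_s[i], tl$onset_s[i] + tl$duration_s[i], NA_real_)
    })
  }
  out <- list()
  for (sp in spans) {
    i0 <- align_event_to_sample(rec$start_time_s + sp[1], rec)
    i1 <- min(as.integer(ceiling(sp[2] * rec$rate_hz)) - 1L,
              ncol(rec$samples) - 1L)
    if (!is.null(mask) && epoch_hits_mask(mask, i0, i1)) next
    out[[length(out) + 1L]] <- list(
      session_id = session$session_id, state = state,
      trial_index = if (is.na(sp[3])) NA_integer_ else as.integer(sp[3]),
      samples = rec$samples[, (i0 + 1L):(i1 + 1L), drop = FALSE],
      rate_hz = rec$rate_hz,
      t0_s = rec$start_time_s + i0 / rec$rate_hz)
  }
  if (length(out) == 0L) {
    warning(sprintf("no %s epochs survive cleaning in session %s",
                    state, session$session_id), call. = FALSE)
  }
  out
}

#' Per-state mean band powers of one session
#'
#' For each requested state, extracts the surviving epochs, estimates each
#' epoch's Welch PSD and integrated band powers, and averages them
#' (unweighted) across epochs. With `relative = TRUE` each epoch's band
#' powers are first normalized by the epoch's total power across the band
#' set.
#'
#' @param session a `cog_session`.
#' @param electrodes channels to analyze (default: all recorded).
#' @param bands band table.
#' @param states states to include.
#' @param mask optional `rejection_mask`.
#' @param window_s,overlap_fraction Welch parameters.
#' @param relative report band powers as fractions of total power.
#' @return a band-power table: data.frame with columns `participant_id`,
#'   `session_id`, `state`, `electrode`, `band`, `mean_power_uV2`,
#'   `n_epochs`.
#' @export
session_band_power <- function(session,
                               electrodes = session$recording$channel_labels,
                               bands = default_bands(),
                               states = c("onset", "offset"), mask = NULL,
                               window_s = 2, overlap_fraction = 0.5,
                               relative = FALSE) {
  stopifnot(all(electrodes %in% session$recording$channel_labels))
  rows <- list()
  for (st in states) {
    epochs <- extract_epochs(session, st, mask = mask)
    if (length(epochs) == 0L) next
    acc <- array(0, dim = c(length(electrodes), nrow(bands)),
                 dimnames = list(electrodes, bands$name))
    for (ep in epochs) {
      psd <- welch_psd(ep$samples[electrodes, , drop = FALSE], ep$rate_hz,
                       window_s = window_s,
                       overlap_fraction = overlap_fraction)
      bp <- vapply(bands$name, function(b) band_power(psd, b, bands),
                   numeric(length(electrodes)))
      bp <- matrix(bp, nrow = length(electrodes),
                   dimnames = list(electrodes, bands$name))
      if (relative) bp <- bp / rowSums(bp)
      acc <- acc + bp
    }
    acc <- acc / length(epochs)
    for (e in electrodes) for (b in bands$name) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = session$participant_id,
        session_id = session$session_id, state = st, electrode = e,
        band = b, mean_power_uV2 = acc[e, b], n_epochs = length(epochs),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||%
    data.frame(participant_id = character(), session_id = character(),
               state = character(), electrode = character(),
               band = character(), mean_power_uV2 = numeric(),
               n_epochs = integer())
}

#' Band-power table over a cohort of sessions
#'
#' @param sessions list of `cog_session`s (one per participant).
#' @param ... passed to [session_band_power()].
#' @return row-bound band-power table.
#' @export
cohort_band_power <- function(sessions, ...) {
  do.call(rbind, lapply(sessions, session_band_power, ...))
}

#' Signal-detection behavioral metrics of an n-Back session
#'
#' A press on a matched probe within its window is a hit; no press a miss.
#' A press on an unmatched probe is a false alarm; no press a correct
#' rejection. Accuracy is `(hits + correct rejections) / probes`; mean
#' reaction time is computed over hits only.
#'
#' @param session a `cog_session` with an n-Back sequence and responses.
#' @return one-row data.frame: `participant_id`, `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `accuracy`, `mean_rt_hits_s`
#'   (`NA` when there are no hits).
#' @export
behavioral_metrics <- function(session) {
  stopifnot(inherits(session, "cog_session"))
  if (is.null(session$sequence) || is.null(session$responses)) {
    stop_cs("session %s has no n-Back responses to score", session$session_id)
  }
  rs <- session$responses
  matched <- vapply(session$sequence, function(t) t$matched, logical(1))
  m <- matched[rs$trial_index + 1L]
  hits <- sum(m & rs$pressed)
  misses <- sum(m & !rs$pressed)
  fa <- sum(!m & rs$pressed)
  cr <- sum(!m & !rs$pressed)
  data.frame(participant_id = session$participant_id,
             hits = hits, misses = misses, false_alarms = fa,
             correct_rejections = cr,
             accuracy = (hits + cr) / nrow(rs),
             mean_rt_hits_s = if (hits > 0)
               mean(rs$reaction_time_s[m & rs$pressed]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Correlate cohort band powers with behavior
#'
#' For every selected combination of electrode, band, state, behavioral
#' metric and statistic: joins band-power rows with behavioral rows on
#' participant id, drops participants with missing values pairwise, and
#' computes the correlation with the n actually used. Combinations with
#' fewer than 3 complete pairs are skipped with a warning.
#'
#' @param band_powers a band-power table from [cohort_band_power()].
#' @param behaviors row-bound output of [behavioral_metrics()].
#' @param electrodes,bands,states which signal selections to test.
#' @param metrics behavioral columns to test (e.g. `"mean_rt_hits_s"`,
#'   `"accuracy"`).
#' @param statistics `"spearman"` and/or `"pearson"`.
#' @param adjust add a Benjamini-Hochberg adjusted p-value column.
#' @return data.frame of cohort results: `electrode`, `band`, `state`,
#'   `metric`, `statistic`, `estimate`, `p_value`, `n` (plus `p_adjusted`
#'   when `adjust = TRUE`).
#' @export
correlate_cohort <- function(band_powers, behaviors,
                             electrodes = unique(band_powers$electrode),
                             bands = unique(band_powers$band),
                             states = unique(band_powers$state),
                             metrics = c("mean_rt_hits_s", "accuracy"),
                             statistics = c("spearman", "pearson"),
                             adjust = FALSE) {
  stopifnot(all(metrics %in% names(behaviors)))
  rows <- list()
  for (e in electrodes) for (b in bands) for (st in states) {
    bp <- band_powers[band_powers$electrode == e & band_powers$band == b &
                        band_powers$state == st, ]
    if (nrow(bp) == 0L) next
    for (met in metrics) for (stat in statistics) {
      j <- merge(bp[, c("participant_id", "mean_power_uV2")],
                 behaviors[, c("participant_id", met)],
                 by = "participant_id")
      x <- j$mean_power_uV2; y <- j[[met]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) {
        warning(sprintf("skipping %s/%s/%s vs %s: only %d complete pairs",
                        e, b, st, met, sum(ok)), call. = FALSE)
        next
      }
      res <- if (stat == "spearman") spearman_cor(x[ok], y[ok])
             else pearson_cor(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = e, band = b, state = st, metric = met, statistic = stat,
        estimate = res$estimate, p_value = res$p_value, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(electrode = character(), band = character(),
               state = character(), metric = character(),
               statistic = character(), estimate = numeric(),
               p_value = numeric(), n = integer())
  if (adjust && nrow(out) > 0L) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
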