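# Session assembly: bind one participant and one task run together.
#
# A session holds the composed sequence and timeline, the emulated
# (quantized) recording, the simulated responses and the metadata keys the
# study database tracks. There is no hardware trigger channel on
# consumer-grade headsets, so stimulus-to-sample locking is arithmetic on
# the shared session clock.

#' Map an event onset to a recording sample index
#'
#' `index = floor((event_onset_s - start_time_s) * rate_hz)`, 0-based.
#' The sample-time reconstruction `start_time_s + index / rate_hz` errs by
#' less than one sample period.
#'
#' @param event_onset_s event onset in epoch seconds.
#' @param recording a `raw_recording`.
#' @return 0-based integer sample index.
#' @export
align_event_to_sample <- function(event_onset_s, recording) {
  stopifnot(inherits(recording, "raw_recording"))
  rel <- event_onset_s - recording$start_time_s
  dur <- recording_duration(recording)
  if (rel < 0 || rel >= dur + 1e-9) {
    stop_cs("event onset %g s lies outside the recording span [%g, %g)",
            event_onset_s, recording$start_time_s,
            recording$start_time_s + dur)
  }
  min(as.integer(floor(rel * recording$rate_hz)),
      ncol(recording$samples) - 1L)
}

new_session <- function(session_id, participant_id, task, sequence, timeline,
                        recording, responses, created_at, device_name,
                        extra = list()) {
  structure(list(session_id = session_id, participant_id = participant_id,
                 task = task, sequence = sequence, timeline = timeline,
                 recording = recording, responses = responses,
                 created_at = created_at, device_name = device_name,
                 extra = extra, rejection_mask = NULL),
            class = "cog_session")
}

#' @export
print.cog_session <- function(x, ...) {
  cat(sprintf("<cog_session> %s: participant %s, %s task, %d events, %d responses\n",
              x$session_id, x$participant_id,
              if (inherits(x$task, "task_spec")) x$task$task_type else class(x$task)[1],
              nrow(x$timeline),
              if (is.null(x$responses)) 0L else nrow(x$responses)))
  print(x$recording)
  invisible(x)
}

#' Run one complete simulated session
#'
#' Executes the full acquisition pipeline for a single participant and task:
#' composes the trial sequence and timeline, synthesizes and quantizes the
#' emulated recording, simulates keypress responses (n-Back only), and —
#' when a store is supplied — persists event and response points to the
#' time-indexed store, the recording as an EDF block, and the session record
#' to the metadata side. Fully deterministic given the seeds carried by the
#' spec, truth and responder objects.
#'
#' @param participant a [participant()] record.
#' @param task a [task_spec()] (or a bare `nback_spec` / `eyes_spec` /
#'   `valence_spec`, which is wrapped).
#' @param profile a `device_profile`.
#' @param truth a `participant_truth` for the emulator.
#' @param responder a `responder_model`, or `NULL` for no responses.
#' @param behavioral_engagement engagement value passed to the responder
#'   (defaults to `truth$engagement`).
#' @param session_id identifier; defaults to `"<participant>-<task type>"`.
#' @param start_time_s epoch-seconds start of the recording. Fixed input
#'   rather than wall clock so reruns are byte-identical.
#' @param channels channels to synthesize (default: full montage).
#' @param store optional `cog_store` to persist into.
#' @param quantize whether to quantize the recording (default TRUE).
#' @return a `cog_session`.
#' @export
run_session <- function(participant, task, profile, truth, responder = NULL,
                        behavioral_engagement = NULL, session_id = NULL,
                        start_time_s = 0, channels = profile$channel_labels,
                        store = NULL, quantize = TRUE) {
  stopifnot(inherits(participant, "participant"))
  if (!inherits(task, "task_spec")) {
    type <- switch(class(task)[1], nback_spec = "nback", eyes_spec = "eyes",
                   valence_spec = "valence",
                   stop_cs("task must be a task_spec or a task parameter object"))
    task <- task_spec(type, task)
  }
  spec <- task$parameters
  sequence <- NULL
  if (task$task_type == "nback") {
    sequence <- compose_nback(spec)
    timeline <- build_timeline(sequence, spec)
  } else if (task$task_type == "eyes") {
    timeline <- compose_eyes(spec)
  } else {
    timeline <- compose_valence(spec)
  }
  recording <- synthesize_recording(profile, timeline, truth,
                                    channels = channels,
                                    start_time_s = start_time_s)
  if (quantize) recording <- quantize_recording(recording, profile)
  responses <- NULL
  if (task$task_type == "nback" && !is.null(responder)) {
    responses <- simulate_responses(
      sequence, timeline, responder,
      engagement = behavioral_engagement %||% truth$engagement,
      start_time_s = start_time_s)
  }
  session_id <- session_id %||%
    paste0(participant$participant_id, "-", task$task_type)
  sess <- new_session(session_id, participant$participant_id, task, sequence,
                      timeline, recording, responses,
                      created_at = start_time_s, device_name = profile$name,
                      extra = list(signal_strength = 1, battery_level = 100))
  if (!is.null(store)) store_session(store, sess, profile)
  sess
}

#' Export a session to a directory of portable files
#'
#' Writes `recording.edf` (signals), `timeline.json` (stimulus events),
#' `responses.csv` (keypresses) and `session.json` (metadata). Given
#' identical seeds and start time, re-exporting produces byte-identical
#' files.
#'
#' @param session a `cog_session`.
#' @param dir output directory (created if missing).
#' @param profile the `device_profile` used, for EDF scaling.
#' @return `dir`, invisibly.
#' @export
export_session <- function(session, dir, profile = epoc_default_profile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edf(session$recording, file.path(dir, "recording.edf"), profile)
  write_timeline(session$timeline, file.path(dir, "timeline.json"))
  if (!is.null(session$responses)) {
    utils::write.csv(session$responses, file.path(dir, "responses.csv"),
                     row.names = FALSE)
  }
  meta <- list(session_id = session$session_id,
               participant_id = session$participant_id,
               task_type = session$task$task_type,
               device = session$device_name,
               created_at = session$created_at,
               rate_hz = session$recording$rate_hz,
               n_samples = ncol(session$recording$samples),
               channels = session$recording$channel_labels,
               extra = session$extra)
  write_json_file(meta, file.path(dir, "session.json"))
  invisible(dir)
}

#' Import a session exported with [export_session()]
#'
#' Rebuilds a `cog_session` from `recording.edf`, `timeline.json`,
#' `responses.csv` and `session.json`. The trial sequence is reconstructed
#' only to the extent the timeline records it (matched flags and trial
#' types from the probe/display payloads), which is sufficient for
#' behavioral scoring and epoching.
#'
#' @param dir directory written by [export_session()].
#' @return a `cog_session`.
#' @export
import_session <- function(dir) {
  meta <- read_json_file(file.path(dir, "session.json"))
  timeline <- read_timeline(file.path(dir, "timeline.json"))
  recording <- read_edf(file.path(dir, "recording.edf"),
                        n_samples = meta$n_samples)
  recording$start_time_s <- meta$created_at
  resp_path <- file.path(dir, "responses.csv")
  responses <- if (file.exists(resp_path)) {
    utils::read.csv(resp_path, stringsAsFactors = FALSE)
  } else NULL
  main_probes <- timeline[timeline$kind == "probe" &
                            !is.na(timeline$trial_index), ]
  sequence <- NULL
  if (nrow(main_probes) > 0L) {
    ord <- order(main_probes$trial_index)
    sequence <- lapply(seq_len(nrow(main_probes)), function(k) {
      i <- ord[k]
      list(index = main_probes$trial_index[i],
           matched = isTRUE(as.logical(main_probes$payload[[i]]$matched)),
           probe = main_probes$payload[[i]]$probe)
    })
    class(sequence) <- "trial_sequence"
  }
  new_session(meta$session_id, meta$participant_id,
              task = structure(list(task_type = meta$task_type,
                                    parameters = NULL),
                               class = "task_spec"),
              sequence = sequence, timeline = timeline,
              recording = recording, responses = responses,
              created_at = meta$created_at, device_name = meta$device,
              extra = meta$extra %||% list())
}
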