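# Event timelines: the absolute-time schedule of a task run.
#
# A timeline is a data.frame of events ordered by onset, with a list-column
# payload. Onsets are seconds relative to session start; intervals are
# half-open [onset, onset + duration).

new_event_timeline <- function(onset_s, duration_s, kind, trial_index, payload) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   kind = as.character(kind),
                   trial_index = as.integer(trial_index),
                   stringsAsFactors = FALSE)
  ev$payload <- payload
  stopifnot(!is.unsorted(ev$onset_s))
  class(ev) <- c("event_timeline", "data.frame")
  ev
}

timeline_kinds <- c("display", "probe", "rest", "instruction",
                    "eyes_open_cue", "eyes_close_cue", "image")

#' Total span of an event timeline in seconds
#' @param timeline an `event_timeline`.
#' @return end time of the last event (seconds from session start).
#' @export
timeline_duration <- function(timeline) {
  if (nrow(timeline) == 0L) return(0)
  max(timeline$onset_s + timeline$duration_s)
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("<event_timeline> %d events over %.1f s\n",
              nrow(x), timeline_duration(x)))
  print(table(kind = x$kind))
  invisible(x)
}

#' Build the absolute-time event schedule of an n-Back run
#'
#' Lays out practice trials (flagged `practice = TRUE` in the payload, with
#' `trial_index = NA`) followed by the composed main block. Every display and
#' probe occupies one `stimulus_interval_s` slot, and a rest event of
#' `rest_duration_s` follows every `rest_every`-th main trial (including
#' after the final trial when the total is a multiple of `rest_every`).
#' Practice trials are drawn with a seed derived from `spec$seed`, so the
#' full schedule is deterministic.
#'
#' @param sequence a `trial_sequence` from [compose_nback()].
#' @param spec the `nback_spec` the sequence was composed from.
#' @return an `event_timeline` with `display`, `probe` and `rest` events.
#' @export
build_timeline <- function(sequence, spec) {
  stopifnot(inherits(sequence, "trial_sequence"), inherits(spec, "nback_spec"))
  slot <- spec$stimulus_interval_s
  practice <- if (spec$practice_trials > 0L) {
    with_seed(derive_seeds(spec$seed, 2L)[2L], {
      types <- spec$n + sample(0:3, spec$practice_trials, replace = TRUE)
      matched <- stats::runif(spec$practice_trials) < 0.5
      lapply(seq_len(spec$practice_trials), function(i) {
        compose_one_trial(spec$n, types[i], matched[i], spec$word_pool,
                          spec$lure_probability)
      })
    })
  } else list()

  onset <- list(); dur <- list(); kind <- list(); tidx <- list(); pay <- list()
  t <- 0
  emit <- function(o, d, k, ti, p) {
    onset[[length(onset) + 1L]] <<- o
    dur[[length(dur) + 1L]] <<- d
    kind[[length(kind) + 1L]] <<- k
    tidx[[length(tidx) + 1L]] <<- ti
    pay[[length(pay) + 1L]] <<- p
  }
  emit_trial <- function(tr, ti, is_practice) {
    for (dsp in tr$displays) {
      emit(t, slot, "display", ti,
           list(words = dsp, practice = is_practice))
      t <<- t + slot
    }
    emit(t, slot, "probe", ti,
         list(probe = tr$probe, matched = tr$matched,
              response_window_s = slot, practice = is_practice))
    t <<- t + slot
  }
  for (tr in practice) emit_trial(tr, NA_integer_, TRUE)
  for (i in seq_along(sequence)) {
    emit_trial(sequence[[i]], sequence[[i]]$index, FALSE)
    if (i %% spec$rest_every == 0L) {
      emit(t, spec$rest_duration_s, "rest", NA_integer_, list())
      t <- t + spec$rest_duration_s
    }
  }
  new_event_timeline(unlist(onset), unlist(dur), unlist(kind),
                     unlist(tidx), pay)
}

#' Specify and compose an eyes-open/closed resting task
#'
#' Alternating verbal cues to open or close the eyes, each held for a fixed
#' interval over a fixed number of trials.
#'
#' @param trial_count number of cues (>= 1).
#' @param interval_s seconds each eye state is held.
#' @param start_state `"open"` or `"closed"`.
#' @param seed integer seed (the schedule itself is deterministic).
#' @return `eyes_spec()` returns an `eyes_spec`; `compose_eyes()` an
#'   `event_timeline` of alternating `eyes_open_cue` / `eyes_close_cue`
#'   events.
#' @export
eyes_spec <- function(trial_count, interval_s = 30,
                      start_state = c("open", "closed"), seed = 1L) {
  start_state <- match.arg(start_state)
  stopifnot(trial_count >= 1, trial_count == round(trial_count), interval_s > 0)
  structure(list(trial_count = as.integer(trial_count),
                 interval_s = interval_s, start_state = start_state,
                 seed = as.integer(seed)),
            class = "eyes_spec")
}

#' @rdname eyes_spec
#' @param spec an `eyes_spec`.
#' @export
compose_eyes <- function(spec) {
  stopifnot(inherits(spec, "eyes_spec"))
  states <- rep(c(spec$start_state,
                  if (spec$start_state == "open") "closed" else "open"),
                length.out = spec$trial_count)
  kinds <- ifelse(states == "open", "eyes_open_cue", "eyes_close_cue")
  onsets <- (seq_len(spec$trial_count) - 1L) * spec$interval_s
  new_event_timeline(onsets, rep(spec$interval_s, spec$trial_count), kinds,
                     rep(NA_integer_, spec$trial_count),
                     lapply(states, function(s) list(state = s)))
}

#' Specify and compose an affective-valence picture task
#'
#' One placeholder image stimulus per id, shown in seeded-shuffled order for
#' a fixed duration; participants classify each picture as unpleasant,
#' neutral or pleasant within the response window.
#'
#' @param image_ids non-empty character vector of stimulus identifiers
#'   (placeholders for a standardized affective image set).
#' @param display_duration_s seconds each image is shown.
#' @param response_window_s response window per image.
#' @param seed integer seed for the presentation order.
#' @return `valence_spec()` returns a `valence_spec`; `compose_valence()` an
#'   `event_timeline` of `image` events.
#' @export
valence_spec <- function(image_ids, display_duration_s = 6,
                         response_window_s = display_duration_s, seed = 1L) {
  if (length(image_ids) == 0L) stop_cs("image_ids must be non-empty")
  stopifnot(display_duration_s > 0, response_window_s > 0)
  structure(list(image_ids = as.character(image_ids),
                 display_duration_s = display_duration_s,
                 response_window_s = response_window_s,
                 valence_labels = c("unpleasant", "neutral", "pleasant"),
                 seed = as.integer(seed)),
            class = "valence_spec")
}

#' @rdname valence_spec
#' @param spec a `valence_spec`.
#' @export
compose_valence <- function(spec) {
  stopifnot(inherits(spec, "valence_spec"))
  order_ids <- with_seed(spec$seed, sample(spec$image_ids))
  n <- length(order_ids)
  onsets <- (seq_len(n) - 1L) * spec$display_duration_s
  new_event_timeline(onsets, rep(spec$display_duration_s, n),
                     rep("image", n), rep(NA_integer_, n),
                     lapply(order_ids, function(id) {
                       list(image_id = id,
                            response_window_s = spec$response_window_s,
                            response_options = spec$valence_labels)
                     }))
}

#' Write or read an event timeline as JSON
#'
#' @param timeline an `event_timeline`.
#' @param path file path.
#' @return `read_timeline` returns an `event_timeline`; `write_timeline`
#'   returns `path` invisibly.
#' @export
write_timeline <- function(timeline, path) {
  events <- lapply(seq_len(nrow(timeline)), function(i) {
    list(onset_s = timeline$onset_s[i],
         duration_s = timeline$duration_s[i],
         kind = timeline$kind[i],
         trial_index = if (is.na(timeline$trial_index[i])) NULL
                       else timeline$trial_index[i],
         payload = timeline$payload[[i]])
  })
  jsonlite::write_json(list(events = events), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)$events
  new_event_timeline(
    vapply(x, function(e) e$onset_s, numeric(1)),
    vapply(x, function(e) e$duration_s, numeric(1)),
    vapply(x, function(e) e$kind, character(1)),
    vapply(x, function(e) as.integer(e$trial_index %||% NA_integer_), integer(1)),
    lapply(x, function(e) {
      p <- e$payload
      # un-box scalar payload entries parsed as length-1 lists
      lapply(p, function(v) if (is.list(v)) unlist(v) else v)
    })
  )
}
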