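# Two-store persistence, self-contained in one directory.
#
# The study database splits into two contracts mirrored here without any
# external service: a schema-less time-indexed point store (measurements
# tagged with free-form string tags, carrying arbitrary named fields) and a
# relational metadata store for participants, groups, task specs and session
# records with referential integrity. Points live in memory and persist as
# JSON-lines; metadata persists as JSON files; whole recordings are stored
# as EDF blocks next to them.
#
# Directory layout:
#   points.jsonl        one point per line
#   participants.json   keyed participant records
#   groups.json         keyed group records
#   taskspecs.json      keyed task specifications
#   sessions.json       session metadata records
#   blocks/<id>.edf     bulk recording blocks

#' Construct a time-indexed data point
#'
#' @param measurement non-empty measurement name.
#' @param timestamp_s epoch seconds (stored at microsecond resolution).
#' @param tags named character list/vector identifying the series
#'   (e.g. `session_id`, `electrode`).
#' @param fields non-empty named list of numeric or string values.
#' @return a `cog_point`.
#' @export
point <- function(measurement, timestamp_s, tags = list(), fields) {
  if (!is.character(measurement) || !nzchar(measurement)) {
    stop_cs("point measurement must be a non-empty string")
  }
  if (!is.numeric(timestamp_s) || !is.finite(timestamp_s)) {
    stop_cs("point timestamp must be finite")
  }
  fields <- as.list(fields)
  if (length(fields) == 0L || is.null(names(fields)) || any(!nzchar(names(fields)))) {
    stop_cs("point fields must be a non-empty named list")
  }
  tags <- lapply(as.list(tags), as.character)
  structure(list(measurement = measurement,
                 timestamp_s = round(timestamp_s * 1e6) / 1e6,
                 tags = tags, fields = fields),
            class = "cog_point")
}

point_key <- function(p) {
  tg <- p$tags[order(names(p$tags))]
  paste(p$measurement, sprintf("%.6f", p$timestamp_s),
        paste(names(tg), unlist(tg), sep = "=", collapse = ","), sep = "|")
}

#' Open (or create) a store directory
#'
#' Loads any existing points and metadata from `dir` into memory. All write
#' operations update memory and the backing files immediately, so a reopened
#' store reproduces its state exactly.
#'
#' @param dir store directory; created if missing.
#' @return a `cog_store` handle.
#' @export
store_open <- function(dir) {
  dir.create(file.path(dir, "blocks"), recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$dir <- dir
  st$points <- list()   # named by point_key
  st$participants <- list()
  st$groups <- list()
  st$taskspecs <- list()
  st$sessions <- list()
  pfile <- file.path(dir, "points.jsonl")
  if (file.exists(pfile)) {
    for (ln in readLines(pfile)) {
      x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      p <- point(x$measurement, x$timestamp_s, x$tags, x$fields)
      st$points[[point_key(p)]] <- p
    }
  }
  for (nm in c("participants", "groups", "taskspecs", "sessions")) {
    f <- file.path(dir, paste0(nm, ".json"))
    if (file.exists(f)) st[[nm]] <- jsonlite::read_json(f, simplifyVector = FALSE)
  }
  class(st) <- "cog_store"
  st
}

flush_points <- function(store) {
  pts <- store$points
  if (length(pts) > 0L) pts <- pts[order(names(pts))]
  lines <- vapply(pts, function(p) {
    jsonlite::toJSON(list(measurement = p$measurement,
                          timestamp_s = p$timestamp_s,
                          tags = p$tags, fields = p$fields),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, file.path(store$dir, "points.jsonl"))
}

flush_meta <- function(store, what) {
  jsonlite::write_json(store[[what]],
                       file.path(store$dir, paste0(what, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Write points to the store
#'
#' Duplicate `(measurement, timestamp, tags)` keys overwrite
#' (last-writer-wins). Invalid points are rejected with the index of the
#' offending point and nothing is written.
#'
#' @param store a `cog_store`.
#' @param points list of [point()] objects.
#' @return number of points written.
#' @export
write_points <- function(store, points) {
  stopifnot(inherits(store, "cog_store"))
  if (length(points) == 0L) return(0L)
  for (i in seq_along(points)) {
    if (!inherits(points[[i]], "cog_point")) {
      stop_cs("invalid point at index %d: not a cog_point", i)
    }
  }
  for (p in points) store$points[[point_key(p)]] <- p
  flush_points(store)
  length(points)
}

#' Query points in a half-open time range
#'
#' Returns exactly the points of `measurement` with
#' `t_start_s <= timestamp < t_end_s` whose tags match every entry of
#' `tag_filters`, in ascending timestamp order. Points with differing field
#' sets coexist (the store is schema-less).
#'
#' @param store a `cog_store`.
#' @param measurement measurement name.
#' @param t_start_s,t_end_s half-open time range, `t_start_s <= t_end_s`.
#' @param tag_filters named list of required tag values.
#' @return list of `cog_point`s sorted by timestamp.
#' @export
query_range <- function(store, measurement, t_start_s, t_end_s,
                        tag_filters = list()) {
  stopifnot(inherits(store, "cog_store"), t_start_s <= t_end_s)
  hit <- Filter(function(p) {
    if (p$measurement != measurement) return(FALSE)
    if (p$timestamp_s < t_start_s || p$timestamp_s >= t_end_s) return(FALSE)
    for (nm in names(tag_filters)) {
      if (is.null(p$tags[[nm]]) || p$tags[[nm]] != tag_filters[[nm]]) {
        return(FALSE)
      }
    }
    TRUE
  }, store$points)
  hit <- unname(hit)
  hit[order(vapply(hit, function(p) p$timestamp_s, numeric(1)))]
}

# ---- relational metadata -------------------------------------------------

#' Metadata CRUD: participants, groups, task specs
#'
#' `save_*` insists on a fresh id unless `overwrite = TRUE`; `load_*` errors
#' on unknown ids; `delete_participant` refuses while any group still
#' references the participant; `save_group` requires every member id to
#' resolve. All writes persist immediately.
#'
#' @param store a `cog_store`.
#' @param p,g a [participant()] / [participant_group()] record.
#' @param participant_id,group_id,task_id record identifier.
#' @param task a [task_spec()].
#' @param overwrite replace an existing record of the same id.
#' @return the saved/loaded record; `list_*` return character vectors of
#'   ids; deletes return `TRUE` invisibly.
#' @name metadata-crud
NULL

#' @rdname metadata-crud
#' @export
save_participant <- function(store, p, overwrite = FALSE) {
  stopifnot(inherits(store, "cog_store"), inherits(p, "participant"))
  id <- p$participant_id
  if (!overwrite && !is.null(store$participants[[id]])) {
    stop_cs("participant id '%s' already exists", id)
  }
  store$participants[[id]] <- unclass(p)
  flush_meta(store, "participants")
  invisible(p)
}

#' @rdname metadata-crud
#' @export
load_participant <- function(store, participant_id) {
  x <- store$participants[[participant_id]]
  if (is.null(x)) stop_cs("no participant with id '%s'", participant_id)
  participant(x$participant_id,
              age = if (is.null(x$age)) NA_integer_ else x$age,
              education_level = if (is.null(x$education_level))
                NA_character_ else x$education_level,
              extra = x$extra %||% list())
}

#' @rdname metadata-crud
#' @export
list_participants <- function(store) names(store$participants)

#' @rdname metadata-crud
#' @export
delete_participant <- function(store, participant_id) {
  if (is.null(store$participants[[participant_id]])) {
    stop_cs("no participant with id '%s'", participant_id)
  }
  referees <- Filter(function(g) participant_id %in% unlist(g$participant_ids),
                     store$groups)
  if (length(referees) > 0L) {
    stop_cs("participant '%s' is still referenced by group(s): %s",
            participant_id,
            paste(vapply(referees, `[[`, "", "group_id"), collapse = ", "))
  }
  store$participants[[participant_id]] <- NULL
  flush_meta(store, "participants")
  invisible(TRUE)
}

#' @rdname metadata-crud
#' @export
save_group <- function(store, g, overwrite = FALSE) {
  stopifnot(inherits(store, "cog_store"), inherits(g, "participant_group"))
  if (!overwrite && !is.null(store$groups[[g$group_id]])) {
    stop_cs("group id '%s' already exists", g$group_id)
  }
  missing <- setdiff(g$participant_ids, names(store$participants))
  if (length(missing) > 0L) {
    stop_cs("group references unknown participant(s): %s",
            paste(missing, collapse = ", "))
  }
  store$groups[[g$group_id]] <- unclass(g)
  flush_meta(store, "groups")
  invisible(g)
}

#' @rdname metadata-crud
#' @export
load_group <- function(store, group_id) {
  x <- store$groups[[group_id]]
  if (is.null(x)) stop_cs("no group with id '%s'", group_id)
  participant_group(x$group_id, name = x$name %||% x$group_id,
                    description = x$description %||% "",
                    participant_ids = unlist(x$participant_ids) %||% character())
}

#' @rdname metadata-crud
#' @export
list_groups <- function(store) names(store$groups)

#' @rdname metadata-crud
#' @export
delete_group <- function(store, group_id) {
  if (is.null(store$groups[[group_id]])) {
    stop_cs("no group with id '%s'", group_id)
  }
  store$groups[[group_id]] <- NULL
  flush_meta(store, "groups")
  invisible(TRUE)
}

#' @rdname metadata-crud
#' @export
save_task_spec <- function(store, task_id, task, overwrite = FALSE) {
  stopifnot(inherits(store, "cog_store"), inherits(task, "task_spec"))
  if (!overwrite && !is.null(store$taskspecs[[task_id]])) {
    stop_cs("task id '%s' already exists", task_id)
  }
  store$taskspecs[[task_id]] <- list(task_type = task$task_type,
                                     parameters = unclass(task$parameters))
  flush_meta(store, "taskspecs")
  invisible(task)
}

#' @rdname metadata-crud
#' @export
load_task_spec <- function(store, task_id) {
  x <- store$taskspecs[[task_id]]
  if (is.null(x)) stop_cs("no task spec with id '%s'", task_id)
  pars <- lapply(x$parameters, function(v) if (is.list(v)) unlist(v) else v)
  params <- switch(x$task_type,
    nback = nback_spec(pars$n, pars$total_trials, pars$stimulus_interval_s,
                       pars$rest_every, pars$rest_duration_s,
                       pars$practice_trials, pars$word_pool,
                       pars$type_fractions, pars$lure_probability, pars$seed),
    eyes = eyes_spec(pars$trial_count, pars$interval_s, pars$start_state,
                     pars$seed),
    valence = valence_spec(pars$image_ids, pars$display_duration_s,
                           pars$response_window_s, pars$seed))
  task_spec(x$task_type, params)
}

#' @rdname metadata-crud
#' @export
list_task_specs <- function(store) names(store$taskspecs)

# ---- session persistence -------------------------------------------------

#' Persist a session into a store
#'
#' Writes the stimulus events and keypress responses as time-indexed points
#' (measurements `"task_event"` and `"response"`, tagged by session id), the
#' recording as an EDF block under `blocks/`, and the session metadata
#' record. The participant record is created on first sight.
#'
#' @param store a `cog_store`.
#' @param session a `cog_session`.
#' @param profile the `device_profile`, for EDF scaling.
#' @return the session id, invisibly.
#' @export
store_session <- function(store, session, profile = epoc_default_profile()) {
  stopifnot(inherits(store, "cog_store"), inherits(session, "cog_session"))
  if (is.null(store$participants[[session$participant_id]])) {
    save_participant(store, participant(session$participant_id))
  }
  t0 <- session$recording$start_time_s
  ev_pts <- lapply(seq_len(nrow(session$timeline)), function(i) {
    point("task_event", t0 + session$timeline$onset_s[i],
          tags = list(session_id = session$session_id,
                      kind = session$timeline$kind[i]),
          fields = list(duration_s = session$timeline$duration_s[i],
                        trial_index = session$timeline$trial_index[i] %||%
                          NA_integer_))
  })
  write_points(store, ev_pts)
  if (!is.null(session$responses) && nrow(session$responses) > 0L) {
    rs <- session$responses[session$responses$pressed, , drop = FALSE]
    if (nrow(rs) > 0L) {
      write_points(store, lapply(seq_len(nrow(rs)), function(i) {
        point("response", rs$timestamp_s[i],
              tags = list(session_id = session$session_id),
              fields = list(trial_index = rs$trial_index[i],
                            reaction_time_s = rs$reaction_time_s[i]))
      }))
    }
  }
  write_edf(session$recording,
            file.path(store$dir, "blocks", paste0(session$session_id, ".edf")),
            profile)
  store$sessions[[session$session_id]] <- list(
    session_id = session$session_id,
    participant_id = session$participant_id,
    task_type = session$task$task_type,
    device = session$device_name,
    created_at = session$created_at,
    edf_block = file.path("blocks", paste0(session$session_id, ".edf")),
    extra = session$extra)
  flush_meta(store, "sessions")
  invisible(session$session_id)
}

#' @export
print.cog_store <- function(x, ...) {
  cat(sprintf("<cog_store> %s: %d points, %d participants, %d groups, %d tasks, %d sessions\n",
              x$dir, length(x$points), length(x$participants),
              length(x$groups), length(x$taskspecs), length(x$sessions)))
  invisible(x)
}
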