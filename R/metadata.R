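#' Participant, group and task-spec metadata records
#'
#' Lightweight validated records mirroring the relational side of the study
#' database: participants (id, age, education level plus free-form extras),
#' named groups of participants, and task specifications. The free-form
#' `extra` map keeps the records schema-flexible, since different tasks and
#' headsets attach different attributes.
#'
#' @param participant_id,group_id unique identifier.
#' @param age nonnegative integer age in years.
#' @param education_level free-text education level.
#' @param extra named list of additional key/value attributes.
#' @param name,description group display fields.
#' @param participant_ids character vector of member participant ids.
#' @return a `participant` / `participant_group` object.
#' @export
participant <- function(participant_id, age = NA_integer_,
                        education_level = NA_character_, extra = list()) {
  stopifnot(is.character(participant_id), nzchar(participant_id))
  if (!is.na(age) && (age < 0 || age != round(age))) {
    stop_cs("age must be a nonnegative integer")
  }
  structure(list(participant_id = participant_id,
                 age = as.integer(age),
                 education_level = as.character(education_level),
                 extra = as.list(extra)),
            class = "participant")
}

#' @rdname participant
#' @export
participant_group <- function(group_id, name = group_id, description = "",
                              participant_ids = character()) {
  stopifnot(is.character(group_id), nzchar(group_id))
  structure(list(group_id = group_id, name = name,
                 description = description,
                 participant_ids = as.character(participant_ids)),
            class = "participant_group")
}

#' Construct a typed task specification wrapper
#'
#' Binds a task type tag (`nback`, `eyes` or `valence`) to its parameter
#' object and validates the parameters against the type's schema.
#'
#' @param task_type one of `"nback"`, `"eyes"`, `"valence"`.
#' @param parameters the matching spec object ([nback_spec()], [eyes_spec()]
#'   or [valence_spec()]).
#' @return a `task_spec` object.
#' @export
task_spec <- function(task_type = c("nback", "eyes", "valence"), parameters) {
  task_type <- match.arg(task_type)
  expected <- switch(task_type, nback = "nback_spec",
                     eyes = "eyes_spec", valence = "valence_spec")
  if (!inherits(parameters, expected)) {
    stop_cs("parameters for task_type '%s' must be a %s object",
            task_type, expected)
  }
  structure(list(task_type = task_type, parameters = parameters),
            class = "task_spec")
}
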