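#' Read and write trial-record tables
#'
#' Trial records travel as comma-separated text with a header row. Columns
#' (units documented once here): `participant`, `material`, `instructions`,
#' `block`, `block_pair`, `trial_in_block`, `stimulus` (1-based location,
#' left to right), `trial_type`, `block_kind`, `predicted` (sequence-
#' predicted location), `pressed`, `rt_ms` (response time in milliseconds),
#' `correct`, `deadline_ms`, `deadline_exceeded`, `post_feedback`,
#' `motor_regular`. Logical columns are stored as TRUE/FALSE and round-trip
#' losslessly.
#'
#' @param trials A trial-record data.frame.
#' @param path File path.
#' @return `read_trials()` returns the data.frame; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

trial_schema <- function() {
  c(participant = "character", material = "character",
    instructions = "character", block = "integer", block_pair = "integer",
    trial_in_block = "integer", stimulus = "integer",
    trial_type = "character", block_kind = "character",
    predicted = "integer", pressed = "integer", rt_ms = "numeric",
    correct = "logical", deadline_ms = "numeric",
    deadline_exceeded = "logical", post_feedback = "logical",
    motor_regular = "logical")
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  schema <- trial_schema()
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
                        character = as.character(df[[col]]),
                        integer = as.integer(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        logical = as.logical(df[[col]]))
  }
  df
}

#' @rdname write_trials
#' @param participants A participant table (one row per participant).
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("belief_sequenced" %in% names(df))
    df$belief_sequenced <- as.logical(df$belief_sequenced)
  df
}

#' Design-configuration round trip through plain text
#'
#' Serializes a [design_config()] to YAML (scalars plus the deadline ramp as
#' a small table) and reads it back.
#'
#' @param config A `design_config`.
#' @param path File path.
#' @export
write_design_config <- function(config, path) {
  lst <- unclass(config)
  if (!is.null(lst$deadline_schedule))
    lst$deadline_schedule <- as.list(lst$deadline_schedule)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sched <- if (!is.null(lst$deadline_schedule))
    data.frame(deadline_ms = lst$deadline_schedule$deadline_ms,
               n_trials = as.integer(lst$deadline_schedule$n_trials))
  design_config(
    n_locations = lst$n_locations, n_blocks = lst$n_blocks,
    trials_per_block = lst$trials_per_block, p_regular = lst$p_regular,
    rsi = lst$rsi, deadline_schedule = sched,
    deadline_main = lst$deadline_main, material = lst$material,
    instructions = lst$instructions, practice_cycles = lst$practice_cycles,
    nonregular_excludes_successor = lst$nonregular_excludes_successor)
}
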