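#' @keywords internal
"_PACKAGE"

#' @importFrom stats AIC dnorm logLik median pnorm qnorm quantile rnorm runif
#'   sd setNames t.test rbinom
#' @importFrom utils combn head
NULL

# Controlled vocabularies for annotated call events.
PHASE_LEVELS <- c("PRE", "F2F", "POST")
VOCAL_TYPES <- c("call", "song", "trill")

#' Construct a table of annotated call events
#'
#' A call event is one vocalization: which bird produced it, when it started
#' and ended (seconds from the start of its experimental phase), its vocal
#' type, and the session and phase it belongs to. Events are validated and
#' returned sorted by onset within each session and phase, with ties broken
#' by caller id.
#'
#' @param session_id Character vector of session identifiers.
#' @param phase Character vector; one of `"PRE"`, `"F2F"`, `"POST"`.
#' @param caller_id Character vector of bird identifiers.
#' @param onset,offset Numeric vectors, seconds from phase start. Each
#'   `offset` must exceed its `onset`, and both must lie in
#'   `[0, phase_duration]`.
#' @param vocal_type Character vector; one of `"call"`, `"song"`, `"trill"`.
#' @param phase_duration Phase length in seconds (default 900, i.e. 15 min).
#'
#' @return A tibble with class `call_events` and the six columns above,
#'   sorted by (session_id, phase, onset, caller_id).
#' @export
call_events <- function(session_id, phase, caller_id, onset, offset,
                        vocal_type = "call", phase_duration = 900) {
  events <- tibble::tibble(
    session_id = as.character(session_id),
    phase = as.character(phase),
    caller_id = as.character(caller_id),
    onset = as.numeric(onset),
    offset = as.numeric(offset),
    vocal_type = as.character(vocal_type)
  )
  validate_call_events(events, phase_duration = phase_duration)
}

#' Validate and sort a call-event table
#'
#' @param events A data frame with columns session_id, phase, caller_id,
#'   onset, offset, vocal_type.
#' @param phase_duration Phase length in seconds used for the range check.
#' @return The validated events as a sorted `call_events` tibble.
#' @export
validate_call_events <- function(events, phase_duration = 900) {
  required <- c("session_id", "phase", "caller_id", "onset", "offset",
                "vocal_type")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- tibble::as_tibble(events)[required]

  bad_phase <- !events$phase %in% PHASE_LEVELS
  if (any(bad_phase)) {
    stop("unknown phase label(s) in row(s) ",
         paste(which(bad_phase), collapse = ", "), ": ",
         paste(unique(events$phase[bad_phase]), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- !events$vocal_type %in% VOCAL_TYPES
  if (any(bad_type)) {
    stop("unknown vocal_type label(s) in row(s) ",
         paste(which(bad_type), collapse = ", "), call. = FALSE)
  }
  bad_order <- events$offset <= events$onset
  if (any(bad_order)) {
    stop("offset must exceed onset; violated in row(s) ",
         paste(which(bad_order), collapse = ", "), call. = FALSE)
  }
  out_of_range <- events$onset < 0 | events$offset > phase_duration
  if (any(out_of_range)) {
    stop("event times outside [0, ", phase_duration, "] in row(s) ",
         paste(which(out_of_range), collapse = ", "), call. = FALSE)
  }

  events <- events[order(events$session_id, match(events$phase, PHASE_LEVELS),
                         events$onset, events$caller_id), ]
  class(events) <- c("call_events", class(events))
  events
}

#' Read an annotated call table
#'
#' Two dialects are supported. `"csv"` expects the package's native columns
#' (`session_id, phase, caller_id, onset_s, offset_s, vocal_type`). `"raven"`
#' reads a Raven selection table: tab-separated with a header containing
#' `"Begin Time (s)"` and `"End Time (s)"`; the caller and vocal-type columns
#' are named through `column_map`, and because Raven tables describe a single
#' recording, `session_id` and `phase` are supplied as arguments. Caller
#' identification from audio channels is out of scope, so channel values are
#' mapped to bird ids through `caller_map`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"csv"` or `"raven"`.
#' @param session_id,phase Session id and phase label for Raven tables.
#' @param column_map Named list for the Raven dialect mapping roles to column
#'   names, e.g. `list(caller = "Channel", vocal_type = "Annotation")`. When
#'   `vocal_type` is omitted all rows are read as `"call"`.
#' @param caller_map Optional named character vector translating raw caller /
#'   channel values to bird ids.
#' @param phase_duration Phase length in seconds used for validation.
#' @return A sorted, validated `call_events` tibble.
#' @export
read_call_table <- function(path, dialect = c("csv", "raven"),
                            session_id = NULL, phase = NULL,
                            column_map = list(caller = "Channel",
                                              vocal_type = "Annotation"),
                            caller_map = NULL, phase_duration = 900) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    required <- c("session_id", "phase", "caller_id", "onset_s", "offset_s",
                  "vocal_type")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop("csv call table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    events <- tibble::tibble(
      session_id = as.character(raw$session_id),
      phase = as.character(raw$phase),
      caller_id = as.character(raw$caller_id),
      onset = raw$onset_s,
      offset = raw$offset_s,
      vocal_type = as.character(raw$vocal_type)
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    required <- c("Begin Time (s)", "End Time (s)", column_map$caller)
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop("raven selection table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (is.null(session_id) || is.null(phase)) {
      stop("session_id and phase must be supplied for the raven dialect",
           call. = FALSE)
    }
    vt <- if (!is.null(column_map$vocal_type) &&
              column_map$vocal_type %in% names(raw)) {
      as.character(raw[[column_map$vocal_type]])
    } else {
      "call"
    }
    events <- tibble::tibble(
      session_id = session_id,
      phase = phase,
      caller_id = as.character(raw[[column_map$caller]]),
      onset = raw[["Begin Time (s)"]],
      offset = raw[["End Time (s)"]],
      vocal_type = vt
    )
  }
  if (!is.null(caller_map)) {
    mapped <- unname(caller_map[events$caller_id])
    events$caller_id <- ifelse(is.na(mapped), events$caller_id, mapped)
  }
  validate_call_events(events, phase_duration = phase_duration)
}

#' Write a call-event table to CSV
#'
#' Times are written with 3-decimal (1 ms) precision, sufficient for ~25 ms
#' contact calls; `read_call_table()` on the written file reproduces the
#' event list to 1 ms.
#'
#' @param events A `call_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(events, path) {
  out <- tibble::tibble(
    session_id = events$session_id,
    phase = events$phase,
    caller_id = events$caller_id,
    onset_s = sprintf("%.3f", events$onset),
    offset_s = sprintf("%.3f", events$offset),
    vocal_type = events$vocal_type
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter events by vocal type and phase
#'
#' @param events A `call_events` tibble.
#' @param vocal_type Optional vocal type to keep (e.g. `"call"`).
#' @param phase Optional phase to keep (e.g. `"F2F"`).
#' @return The matching events, original order preserved. An empty result is
#'   legal.
#' @export
filter_events <- function(events, vocal_type = NULL, phase = NULL) {
  keep <- rep(TRUE, nrow(events))
  if (!is.null(vocal_type)) keep <- keep & events$vocal_type %in% vocal_type
  if (!is.null(phase)) keep <- keep & events$phase %in% phase
  events[keep, ]
}

#' Bundle one experimental session
#'
#' A session consists of a subject bird recorded alone in the PRE and POST
#' phases and together with a facing bird in the F2F phase. The record
#' carries the ordered pair (subject first) and the session's events.
#'
#' @param session_id Session identifier.
#' @param subject,facing Bird ids; subject is the bird introduced first.
#' @param events `call_events` for this session (any subset of phases).
#' @param phase_duration Phase length in seconds.
#' @return A `session_record` object.
#' @export
session_record <- function(session_id, subject, facing = NA_character_,
                           events, phase_duration = 900) {
  events <- validate_call_events(events, phase_duration = phase_duration)
  if (!all(events$session_id == session_id)) {
    stop("events carry a session_id other than ", session_id, call. = FALSE)
  }
  solo <- events[events$phase %in% c("PRE", "POST"), ]
  if (nrow(solo) > 0 && !all(solo$caller_id == subject)) {
    stop("PRE/POST events must all belong to the subject ", subject,
         call. = FALSE)
  }
  allowed <- c(subject, if (!is.na(facing)) facing)
  if (!all(events$caller_id %in% allowed)) {
    stop("events from callers outside the pair (",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  structure(
    list(session_id = session_id, subject = subject, facing = facing,
         events = events),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> ", x$session_id, ": subject ", x$subject,
      if (!is.na(x$facing)) paste0(", facing ", x$facing),
      "; ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Pool the event tables of several sessions
#'
#' @param sessions List of `session_record` objects.
#' @return A single `call_events` tibble.
#' @export
bind_session_events <- function(sessions) {
  ev <- dplyr::bind_rows(lapply(sessions, function(s) s$events))
  validate_call_events(ev)
}

#' Analysis configuration defaults
#'
#' Collects the handful of tunable constants the pipeline uses: phase length,
#' the threshold for the "fraction of intervals within x seconds" summary,
#' the logarithm base for interval transforms, the number of Monte-Carlo
#' repetitions and percentile level of the interval test, and the root seed.
#'
#' @param phase_duration Seconds per phase (default 900).
#' @param interval_threshold Seconds, for the fraction-within summary
#'   (default 10).
#' @param log_base Base of the interval log transform (default 10).
#' @param n_permutations Monte-Carlo repetitions (default 10000).
#' @param percentile_level Central percentile level in percent (default 95).
#' @param rng_seed Root seed for all stochastic stages.
#' @return A named list with class `experiment_config`.
#' @export
experiment_config <- function(phase_duration = 900, interval_threshold = 10,
                              log_base = 10, n_permutations = 10000,
                              percentile_level = 95, rng_seed = 1L) {
  stopifnot(phase_duration > 0, interval_threshold > 0, log_base > 1,
            n_permutations >= 100,
            percentile_level > 0, percentile_level < 100)
  structure(
    list(phase_duration = phase_duration,
         interval_threshold = interval_threshold,
         log_base = log_base,
         n_permutations = as.integer(n_permutations),
         percentile_level = percentile_level,
         rng_seed = as.integer(rng_seed)),
    class = "experiment_config"
  )
}
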