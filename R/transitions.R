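# Call transitions: consecutive-call pairs within one session phase.
#
# An exchange transition is a call by one bird followed by a call from the
# other bird; a repeated transition is two consecutive calls by the same
# bird. The inter-call interval runs from the offset of the preceding call
# to the onset of the following call and is negative when the calls overlap.

#' Build the transition sequence of one session phase
#'
#' For N onset-sorted events the function returns the N-1 consecutive pairs,
#' each classified as `exchange` (different callers) or `repeated` (same
#' caller) with its offset-to-onset interval. Transitions never span a
#' session or phase boundary; use [transitions_by_phase()] to process pooled
#' tables.
#'
#' @param events `call_events` from a single session and phase, sorted by
#'   onset.
#' @return A tibble with one row per transition: session_id, phase,
#'   preceding_caller, following_caller, kind, interval (seconds; negative
#'   when the following call starts before the preceding one ends), overlap.
#' @export
build_transitions <- function(events) {
  if (length(unique(events$session_id)) > 1 ||
      length(unique(events$phase)) > 1) {
    stop("events span more than one session or phase; ",
         "build transitions per (session, phase)", call. = FALSE)
  }
  if (is.unsorted(events$onset)) {
    stop("events must be sorted by onset", call. = FALSE)
  }
  n <- nrow(events)
  if (n < 2) return(empty_transitions())
  pre <- events[-n, ]
  fol <- events[-1, ]
  interval <- fol$onset - pre$offset
  tibble::tibble(
    session_id = pre$session_id,
    phase = pre$phase,
    preceding_caller = pre$caller_id,
    following_caller = fol$caller_id,
    kind = ifelse(pre$caller_id == fol$caller_id, "repeated", "exchange"),
    interval = interval,
    overlap = interval < 0
  )
}

empty_transitions <- function() {
  tibble::tibble(
    session_id = character(), phase = character(),
    preceding_caller = character(), following_caller = character(),
    kind = character(), interval = numeric(), overlap = logical()
  )
}

#' Build transitions independently within each (session, phase)
#'
#' Mirrors the pooled analysis: transitions are formed inside each session
#' phase and concatenated, so no transition crosses a recording boundary.
#'
#' @param events A `call_events` tibble, possibly spanning many sessions.
#' @return A transition tibble (see [build_transitions()]).
#' @export
transitions_by_phase <- function(events) {
  if (nrow(events) == 0) return(empty_transitions())
  parts <- split(events, list(events$session_id, events$phase), drop = TRUE)
  dplyr::bind_rows(lapply(parts, build_transitions))
}

#' Partition transitions into exchange and repeated
#'
#' @param transitions A transition tibble.
#' @return A list with elements `exchange` and `repeated`; their row counts
#'   sum to the input count.
#' @export
split_by_kind <- function(transitions) {
  list(exchange = transitions[transitions$kind == "exchange", ],
       repeated = transitions[transitions$kind == "repeated", ])
}

#' Count overlapping transitions
#'
#' An overlap is a negative inter-call interval: the following call starts
#' before the preceding call ends. On single-caller tracks without self
#' overlap these can arise only in exchange transitions.
#'
#' @param transitions A transition tibble.
#' @return Integer count of transitions with `interval < 0`.
#' @export
count_overlaps <- function(transitions) {
  sum(transitions$interval < 0)
}

#' Fraction of intervals within a threshold
#'
#' Proportion of inter-call intervals at or below `threshold` seconds;
#' negative (overlapping) intervals count as within.
#'
#' @param intervals Numeric vector of intervals in seconds.
#' @param threshold Positive threshold in seconds (default 10).
#' @return Proportion in `[0, 1]`.
#' @export
fraction_within <- function(intervals, threshold = 10) {
  stopifnot(threshold > 0)
  if (length(intervals) == 0) {
    stop("fraction_within is undefined for an empty interval list",
         call. = FALSE)
  }
  mean(intervals <= threshold)
}

#' Export a transition table as CSV
#'
#' @param transitions A transition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(transitions, path) {
  out <- transitions[c("session_id", "kind", "preceding_caller",
                       "following_caller", "interval", "overlap")]
  names(out)[names(out) == "interval"] <- "interval_s"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
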