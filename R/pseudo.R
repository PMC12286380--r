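# Pseudo-turn-taking null: re-pair each subject's F2F call track with the
# facing bird's track from a *different* session of the same pair. The two
# tracks become temporally independent while pair identity and each track's
# marginal timing are preserved exactly. A derangement of the pair's
# session indices guarantees no pseudo session reproduces a real one.

#' Seeded uniform random derangement
#'
#' A derangement is a permutation with no fixed points. Sampled by
#' rejection: permutations are drawn uniformly until one has no fixed
#' point, which is fast for the small session counts involved (the
#' acceptance probability tends to 1/e).
#'
#' @param n Number of elements (>= 2).
#' @return An integer permutation `p` of `1:n` with `p[i] != i` for all i.
#' @export
random_derangement <- function(n) {
  if (n < 2) stop("a derangement needs at least 2 elements", call. = FALSE)
  if (n == 2) return(c(2L, 1L))
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Build pseudo-turn-taking sessions
#'
#' For every ordered pair (subject, facing) the F2F sessions are collected
#' and the facing-bird tracks are reassigned across that pair's sessions by
#' a seeded derangement, so each pseudo session merges a subject track with
#' a facing track recorded at a different time. Track clocks are untouched:
#' no time offset is added. One pseudo session is produced per original
#' session.
#'
#' @param sessions List of `session_record` objects with F2F events.
#' @param seed Integer seed for the derangements.
#' @return A list of `pseudo_session` objects, each carrying the merged,
#'   onset-sorted events plus the two source session ids.
#' @export
make_pseudo_sessions <- function(sessions, seed = 1L) {
  pair_key <- vapply(sessions, function(s) paste(s$subject, s$facing),
                     character(1))
  has_facing <- !vapply(sessions, function(s) is.na(s$facing), logical(1))
  if (!all(has_facing)) {
    stop("all sessions must have a facing bird (F2F recordings)",
         call. = FALSE)
  }
  groups <- split(seq_along(sessions), pair_key)
  single <- names(groups)[lengths(groups) < 2]
  if (length(single) > 0) {
    stop("pair(s) with a single F2F session cannot be re-paired: ",
         paste(single, collapse = "; "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (key in names(groups)) {
      idx <- groups[[key]]
      der <- random_derangement(length(idx))
      for (i in seq_along(idx)) {
        s_subj <- sessions[[idx[i]]]
        s_face <- sessions[[idx[der[i]]]]
        f2f_subj <- s_subj$events[s_subj$events$phase == "F2F" &
                                    s_subj$events$caller_id == s_subj$subject, ]
        f2f_face <- s_face$events[s_face$events$phase == "F2F" &
                                    s_face$events$caller_id == s_face$facing, ]
        merged <- rbind(f2f_subj, f2f_face)
        merged$session_id <- paste0("pseudo_", s_subj$session_id)
        merged <- merged[order(merged$onset, merged$caller_id), ]
        out[[length(out) + 1]] <- structure(
          list(session_id = paste0("pseudo_", s_subj$session_id),
               subject = s_subj$subject, facing = s_subj$facing,
               source_subject_session = s_subj$session_id,
               source_facing_session = s_face$session_id,
               events = merged),
          class = c("pseudo_session", "session_record")
        )
      }
    }
    out
  })
}

#' @export
print.pseudo_session <- function(x, ...) {
  cat("<pseudo_session> ", x$session_id, ": subject track from ",
      x$source_subject_session, ", facing track from ",
      x$source_facing_session, "; ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Transition analysis of pseudo-turn-taking sessions
#'
#' Runs the standard transition construction on each merged pseudo track
#' and pools the results for downstream mixture fitting and plotting.
#'
#' @param pseudo_sessions List of `pseudo_session` objects.
#' @param vocal_type Vocal type analysed (default `"call"`).
#' @return A list with `transitions` (pooled tibble), `exchange_intervals`,
#'   `repeated_intervals` and `n_overlap`.
#' @export
pseudo_transition_analysis <- function(pseudo_sessions,
                                       vocal_type = "call") {
  trans <- dplyr::bind_rows(lapply(pseudo_sessions, function(ps) {
    ev <- filter_events(ps$events, vocal_type = vocal_type, phase = "F2F")
    build_transitions(ev)
  }))
  parts <- split_by_kind(trans)
  list(transitions = trans,
       exchange_intervals = parts$exchange$interval,
       repeated_intervals = parts$repeated$interval,
       n_overlap = count_overlaps(trans))
}

#' Export pseudo sessions in the native CSV dialect
#'
#' Written like a real call table with two provenance columns recording the
#' source session of each bird's track.
#'
#' @param pseudo_sessions List of `pseudo_session` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudo_sessions <- function(pseudo_sessions, path) {
  rows <- dplyr::bind_rows(lapply(pseudo_sessions, function(ps) {
    ev <- ps$events
    tibble::tibble(
      session_id = ev$session_id, phase = ev$phase,
      caller_id = ev$caller_id,
      onset_s = sprintf("%.3f", ev$onset),
      offset_s = sprintf("%.3f", ev$offset),
      vocal_type = ev$vocal_type,
      source_subject_session = ps$source_subject_session,
      source_facing_session = ps$source_facing_session
    )
  }))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
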