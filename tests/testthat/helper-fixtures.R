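# Shared fixtures: quick event builders and the published mixture
# parameters used as generating truths in recovery tests.

make_events <- function(onsets, callers, session = "S1", phase = "F2F",
                        dur = 0.02, vocal_type = "call") {
  call_events(session_id = session, phase = phase, caller_id = callers,
              onset = onsets, offset = onsets + dur,
              vocal_type = vocal_type)
}

# published two-component fits on log10 intervals (mean, variance, weight)
TBL_EXCHANGE <- list(short = c(mean = -0.728, var = 0.023, w = 0.322),
                     long = c(mean = 0.321, var = 0.502, w = 0.678))
TBL_REPEATED <- list(short = c(mean = -0.669, var = 0.035, w = 0.167),
                     long = c(mean = 0.578, var = 0.296, w = 0.833))

# draw from a two-component normal mixture on the log10 scale
draw_mixture <- function(n, mix) {
  z <- stats::rbinom(n, 1, mix$short[["w"]])
  ifelse(z == 1,
         stats::rnorm(n, mix$short[["mean"]], sqrt(mix$short[["var"]])),
         stats::rnorm(n, mix$long[["mean"]], sqrt(mix$long[["var"]])))
}

# closed-form mixture CDF on the log10 scale
mixture_cdf <- function(q, mix) {
  mix$short[["w"]] *
    stats::pnorm(q, mix$short[["mean"]], sqrt(mix$short[["var"]])) +
    mix$long[["w"]] *
    stats::pnorm(q, mix$long[["mean"]], sqrt(mix$long[["var"]]))
}

# a session record with scripted F2F tracks for two birds
scripted_session <- function(session_id, subj_onsets, face_onsets,
                             subject = "A", facing = "B", dur = 0.02) {
  ev <- rbind(
    make_events(subj_onsets, subject, session = session_id, dur = dur),
    make_events(face_onsets, facing, session = session_id, dur = dur)
  )
  session_record(session_id, subject, facing, validate_call_events(ev))
}
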