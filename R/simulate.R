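# Seeded simulator of two-bird calling sessions with the statistical
# structure the analysis assumes: each bird calls on its own as a renewal
# process with log10-normal inter-call gaps (the long "independent calling"
# component) and, with some probability, answers its partner's call after a
# log10-normal latency (the short "response" component). Latencies are
# log10-normal on purpose: the analysis fits Gaussian mixtures on log10
# intervals, so parameter recovery is a sharp test rather than an
# approximation.

#' Simulation parameters
#'
#' @param phase_duration Phase length in seconds (default 900).
#' @param baseline_rate Optional baseline calling rate in calls/second.
#'   `NULL` (default) leaves the self-interval distribution as given; a
#'   positive value rescales its log10 mean so the expected gap equals
#'   `1/baseline_rate`; `0` disables baseline calling entirely.
#' @param response_prob Probability in `[0, 1]` that a bird answers its
#'   partner's call. The default 1/3 matches the observed face-to-face
#'   increase in call output over solo calling (about 1.5-fold): responses
#'   form a branching process that multiplies baseline output by
#'   `1 / (1 - response_prob)`.
#' @param response_latency_log10_mean,response_latency_log10_sd Parameters
#'   of the log10-normal response latency, measured from the partner's call
#'   offset to the response onset (defaults -0.73 and 0.15 log10 s, i.e. a
#'   typical latency near 0.19 s).
#' @param self_interval_log10_mean,self_interval_log10_sd Parameters of the
#'   log10-normal gap between a bird's own consecutive calls when calling
#'   independently. The defaults (1.0 and 0.6 log10 s) give a mean gap of
#'   about 26 s, i.e. roughly 35 solo calls per 15-minute phase, matching
#'   observed solo call output.
#' @param call_duration Call length in seconds (default 0.0247, the ~25 ms
#'   contact call).
#' @param refractory Minimum silence a bird keeps after its own call
#'   offset, seconds; must be at least `call_duration` so a bird never
#'   overlaps itself (default 0.05).
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(phase_duration = 900,
                              baseline_rate = NULL,
                              response_prob = 1 / 3,
                              response_latency_log10_mean = -0.73,
                              response_latency_log10_sd = 0.15,
                              self_interval_log10_mean = 1.0,
                              self_interval_log10_sd = 0.6,
                              call_duration = 0.0247,
                              refractory = 0.05) {
  stopifnot(phase_duration > 0, call_duration > 0,
            refractory >= call_duration,
            response_prob >= 0, response_prob <= 1,
            response_latency_log10_sd > 0, self_interval_log10_sd > 0)
  m <- self_interval_log10_mean
  if (!is.null(baseline_rate)) {
    stopifnot(baseline_rate >= 0)
    if (baseline_rate > 0) {
      # rescale the log10 mean so E[gap] = 1/rate, keeping the shape
      target_mean_gap <- 1 / baseline_rate
      cur_mean_gap <- log10normal_mean(m, self_interval_log10_sd)
      m <- m - log10(cur_mean_gap / target_mean_gap)
    }
  }
  structure(
    list(phase_duration = phase_duration,
         baseline_rate = baseline_rate,
         response_prob = response_prob,
         response_latency_log10_mean = response_latency_log10_mean,
         response_latency_log10_sd = response_latency_log10_sd,
         self_interval_log10_mean = m,
         self_interval_log10_sd = self_interval_log10_sd,
         call_duration = call_duration,
         refractory = refractory),
    class = "simulation_params"
  )
}

#' Mean of a log10-normal variable
#'
#' Expected value of `10^X` for `X ~ N(mean, sd^2)`.
#'
#' @param mean,sd Parameters on the log10 scale.
#' @return The mean on the natural (seconds) scale.
#' @export
log10normal_mean <- function(mean, sd) {
  10^mean * exp((sd * log(10))^2 / 2)
}

baseline_disabled <- function(params) {
  !is.null(params$baseline_rate) && params$baseline_rate == 0
}

draw_gap <- function(params) {
  10^rnorm(1, params$self_interval_log10_mean,
           params$self_interval_log10_sd)
}

#' Simulate a two-bird face-to-face phase
#'
#' Event-driven simulation: each bird schedules baseline calls from its
#' renewal process; when a bird's call ends, the partner answers with
#' probability `response_prob` after a log10-normal latency. A response is
#' suppressed when it would fall inside the responder's refractory window,
#' and at most one response is pending per bird. A bird's pending baseline
#' call is rescheduled (not cancelled) after any of its calls, so marginal
#' rates stay interpretable. Fully reproducible given `seed`.
#'
#' @param params A `simulation_params` object.
#' @param session_id,subject,facing Identifiers for the session record.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `session_record` whose events cover the F2F phase.
#' @export
simulate_f2f_session <- function(params, session_id = "S1",
                                 subject = "birdA", facing = "birdB",
                                 seed = NULL) {
  run <- function() {
    simulate_two_track(params, c(subject, facing))
  }
  ev <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())
  events <- make_phase_events(ev, session_id, "F2F",
                              params$call_duration, params$phase_duration)
  session_record(session_id, subject, facing, events,
                 phase_duration = params$phase_duration)
}

# core two-bird loop; returns data.frame(onset, caller_index)
simulate_two_track <- function(params, callers) {
  dur <- params$call_duration
  horizon <- params$phase_duration - dur
  next_base <- if (baseline_disabled(params)) {
    c(Inf, Inf)
  } else {
    c(draw_gap(params), draw_gap(params))
  }
  next_resp <- c(Inf, Inf)
  last_off <- c(-Inf, -Inf)
  onsets <- numeric(0)
  who <- integer(0)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 1e6) stop("simulation exceeded event budget", call. = FALSE)
    cand <- pmin(next_base, next_resp)
    b <- which.min(cand)
    t <- cand[b]
    if (t > horizon) break
    is_resp <- next_resp[b] <= next_base[b]
    if (t < last_off[b] + params$refractory) {
      if (is_resp) {
        next_resp[b] <- Inf # suppressed in the refractory window
      } else {
        next_base[b] <- last_off[b] + params$refractory
      }
      next
    }
    onsets <- c(onsets, t)
    who <- c(who, b)
    off <- t + dur
    last_off[b] <- off
    if (!baseline_disabled(params)) next_base[b] <- off + draw_gap(params)
    if (is_resp) next_resp[b] <- Inf
    p <- 3L - b
    if (runif(1) < params$response_prob && !is.finite(next_resp[p])) {
      next_resp[p] <- off + 10^rnorm(1, params$response_latency_log10_mean,
                                     params$response_latency_log10_sd)
    }
  }
  data.frame(onset = onsets, caller = callers[who],
             stringsAsFactors = FALSE)
}

make_phase_events <- function(track, session_id, phase, call_duration,
                              phase_duration) {
  if (nrow(track) == 0) {
    ev <- tibble::tibble(session_id = character(), phase = character(),
                         caller_id = character(), onset = numeric(),
                         offset = numeric(), vocal_type = character())
    return(validate_call_events(ev, phase_duration))
  }
  ev <- tibble::tibble(
    session_id = session_id, phase = phase, caller_id = track$caller,
    onset = track$onset, offset = track$onset + call_duration,
    vocal_type = "call"
  )
  validate_call_events(ev, phase_duration)
}

#' Simulate a solo (PRE or POST) phase
#'
#' Single-bird renewal process with log10-normal gaps; no responses are
#' possible.
#'
#' @param params A `simulation_params` object.
#' @param session_id,subject Identifiers.
#' @param phase `"PRE"` or `"POST"`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `session_record` with the solo phase's events.
#' @export
simulate_solo_phase <- function(params, session_id = "S1",
                                subject = "birdA", phase = "PRE",
                                seed = NULL) {
  stopifnot(phase %in% c("PRE", "POST"))
  run <- function() {
    dur <- params$call_duration
    horizon <- params$phase_duration - dur
    onsets <- numeric(0)
    if (!baseline_disabled(params)) {
      t <- draw_gap(params)
      while (t <= horizon) {
        onsets <- c(onsets, t)
        t <- t + dur + max(draw_gap(params), params$refractory)
      }
    }
    onsets
  }
  onsets <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())
  ev <- tibble::tibble(
    session_id = session_id, phase = phase, caller_id = subject,
    onset = onsets, offset = onsets + params$call_duration,
    vocal_type = "call"
  )
  session_record(session_id, subject, NA_character_,
                 validate_call_events(ev, params$phase_duration),
                 phase_duration = params$phase_duration)
}

#' Simulate the full pairwise experiment
#'
#' All pairs of `n_subjects` birds, `sessions_per_pair` sessions each (the
#' default design: 6 birds, 15 pairs, 4 sessions, 60 sessions total). Each
#' session has a PRE solo phase for the subject, an F2F phase for the pair,
#' and a POST solo phase. The subject role alternates between the two pair
#' members across a pair's sessions. Optional rate multipliers scale
#' baseline calling in the F2F phase and per subject, for count-model
#' recovery studies.
#'
#' @param params A `simulation_params` object shared by all phases.
#' @param n_subjects Number of birds (default 6).
#' @param sessions_per_pair Sessions per pair (default 4).
#' @param f2f_rate_multiplier Multiplies both birds' baseline rates in the
#'   F2F phase (default 1).
#' @param subject_rate_multipliers Optional named vector of per-bird
#'   baseline-rate multipliers.
#' @param seed Integer root seed.
#' @return A list of `session_record` objects, one per session, each
#'   covering all three phases.
#' @export
simulate_experiment <- function(params = simulation_params(),
                                n_subjects = 6, sessions_per_pair = 4,
                                f2f_rate_multiplier = 1,
                                subject_rate_multipliers = NULL,
                                seed = 1L) {
  stopifnot(n_subjects >= 2, sessions_per_pair >= 1)
  birds <- sprintf("bird%02d", seq_len(n_subjects))
  pairs <- combn(birds, 2)
  withr::with_seed(as.integer(seed), {
    sessions <- list()
    k <- 0L
    for (p in seq_len(ncol(pairs))) {
      for (s in seq_len(sessions_per_pair)) {
        k <- k + 1L
        # alternate which pair member is introduced first, in blocks of
        # two sessions so every ordered (subject, facing) pair appears at
        # least twice (the pseudo-pairing null re-pairs within ordered
        # pairs)
        subject <- pairs[((s - 1) %/% 2) %% 2 + 1, p]
        facing <- setdiff(pairs[, p], subject)
        sid <- sprintf("S%02d_%s_%s_r%d", k, subject, facing, s)
        mult_subj <- rate_multiplier(subject_rate_multipliers, subject)
        mult_face <- rate_multiplier(subject_rate_multipliers, facing)
        pre <- simulate_solo_phase(scale_rate(params, mult_subj), sid,
                                   subject, "PRE")
        f2f <- simulate_f2f_session(
          scale_rate(params, f2f_rate_multiplier),
          sid, subject, facing
        )
        # per-bird multipliers apply to the merged F2F tracks via rates;
        # when both birds share the multiplier this is exact
        post <- simulate_solo_phase(scale_rate(params, mult_subj), sid,
                                    subject, "POST")
        ev <- dplyr::bind_rows(pre$events, f2f$events, post$events)
        sessions[[k]] <- session_record(sid, subject, facing,
                                        validate_call_events(
                                          ev, params$phase_duration),
                                        params$phase_duration)
      }
    }
    sessions
  })
}

rate_multiplier <- function(multipliers, bird) {
  if (is.null(multipliers) || !bird %in% names(multipliers)) 1 else
    multipliers[[bird]]
}

# scale baseline calling rate by shifting the log10 gap mean
scale_rate <- function(params, multiplier) {
  if (multiplier == 1) return(params)
  p <- unclass(params)
  p$self_interval_log10_mean <-
    p$self_interval_log10_mean - log10(multiplier)
  structure(p, class = "simulation_params")
}

#' Simulate a phase-count table directly
#'
#' Draws Poisson counts from the generative model the count GLMM assumes:
#' log-rate = intercept + phase effect + subject intercept + trial
#' intercept. Used for parameter-recovery studies of [fit_count_model()]
#' without running the event-level simulator.
#'
#' @param n_subjects,n_trials Design size (trials nested in subjects).
#' @param baseline_log_rate Intercept on the log scale (default log(35)
#'   calls per phase).
#' @param f2f_effect,post_effect Fixed log rate ratios vs PRE (defaults
#'   log(1.5) and 0).
#' @param subject_sd,trial_sd Random-intercept SDs (defaults 0.3, 0.1).
#' @param seed Integer seed.
#' @return A tibble of (subject_id, trial_id, phase, n_calls) rows.
#' @export
simulate_phase_counts <- function(n_subjects = 6, n_trials = 10,
                                  baseline_log_rate = log(35),
                                  f2f_effect = log(1.5), post_effect = 0,
                                  subject_sd = 0.3, trial_sd = 0.1,
                                  seed = 1L) {
  withr::with_seed(as.integer(seed), {
    subj_fx <- rnorm(n_subjects, 0, subject_sd)
    rows <- list()
    k <- 0L
    for (i in seq_len(n_subjects)) {
      for (j in seq_len(n_trials)) {
        trial_fx <- rnorm(1, 0, trial_sd)
        for (ph in PHASE_LEVELS) {
          k <- k + 1L
          eta <- baseline_log_rate + subj_fx[i] + trial_fx +
            switch(ph, PRE = 0, F2F = f2f_effect, POST = post_effect)
          rows[[k]] <- tibble::tibble(
            subject_id = sprintf("bird%02d", i),
            trial_id = sprintf("bird%02d_t%02d", i, j),
            phase = ph,
            n_calls = stats::rpois(1, exp(eta))
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
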