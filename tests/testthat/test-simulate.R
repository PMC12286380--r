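test_that("simulation is deterministic given parameters and seed", {
  p <- simulation_params()
  s1 <- simulate_f2f_session(p, seed = 11)
  s2 <- simulate_f2f_session(p, seed = 11)
  expect_equal(s1$events, s2$events)
  expect_false(isTRUE(all.equal(s1$events,
                                simulate_f2f_session(p, seed = 12)$events)))
  e1 <- simulate_experiment(n_subjects = 3, sessions_per_pair = 2, seed = 4)
  e2 <- simulate_experiment(n_subjects = 3, sessions_per_pair = 2, seed = 4)
  expect_equal(bind_session_events(e1), bind_session_events(e2))
})

test_that("silent parameter settings produce empty sessions", {
  p <- simulation_params(baseline_rate = 0, response_prob = 0)
  expect_equal(nrow(simulate_f2f_session(p, seed = 1)$events), 0)
  expect_equal(nrow(simulate_solo_phase(p, seed = 1)$events), 0)
})

test_that("a bird never overlaps its own calls and all events fit the phase", {
  p <- simulation_params()
  for (s in 1:5) {
    ev <- simulate_f2f_session(p, seed = 100 + s)$events
    for (bird in unique(ev$caller_id)) {
      track <- ev[ev$caller_id == bird, ]
      if (nrow(track) > 1) {
        gaps <- track$onset[-1] - track$offset[-nrow(track)]
        expect_gte(min(gaps), p$refractory - p$call_duration - 1e-9)
      }
    }
    expect_true(all(ev$offset <= p$phase_duration))
    expect_true(all(ev$onset >= 0))
  }
})

test_that("solo call counts follow the renewal-process rate", {
  p <- simulation_params()
  counts <- vapply(1:50, function(s)
    nrow(simulate_solo_phase(p, seed = 600 + s)$events), numeric(1))
  # renewal theory: N(t) ~ t/mu with var t*sigma^2/mu^3
  lmu <- p$self_interval_log10_mean
  lsd <- p$self_interval_log10_sd
  mu <- log10normal_mean(lmu, lsd) + p$call_duration
  sigma2 <- 10^(2 * lmu) * (exp(2 * (lsd * log(10))^2) -
                              exp((lsd * log(10))^2))
  expected <- p$phase_duration / mu
  se_mean <- sqrt(p$phase_duration * sigma2 / mu^3 / 50)
  expect_lt(abs(mean(counts) - expected), 3 * se_mean + 1)
})

test_that("solo phases yield only repeated transitions", {
  s <- simulate_solo_phase(simulation_params(), seed = 8, phase = "POST")
  tr <- build_transitions(s$events)
  expect_true(all(tr$kind == "repeated"))
  expect_equal(count_overlaps(tr), 0)
})

test_that("exchange overlaps are rare at default parameters and absent for pure responses", {
  p <- simulation_params()
  sess <- lapply(1:20, function(i)
    simulate_f2f_session(p, session_id = paste0("S", i), seed = 700 + i))
  trans <- transitions_by_phase(bind_session_events(sess))
  exch <- split_by_kind(trans)$exchange
  expect_gt(nrow(exch), 500)
  expect_lt(count_overlaps(exch) / nrow(exch), 0.01)

  # with almost no baseline calling, exchanges are response latencies,
  # which start strictly after the partner's offset: no overlaps
  p_resp <- simulation_params(baseline_rate = 1 / 300, response_prob = 1)
  sess_r <- lapply(1:5, function(i)
    simulate_f2f_session(p_resp, session_id = paste0("R", i),
                         seed = 800 + i))
  tr_r <- transitions_by_phase(bind_session_events(sess_r))
  expect_equal(count_overlaps(tr_r), 0)
})

test_that("independent tracks carry no short-latency exchange mass", {
  p0 <- simulation_params(response_prob = 0)
  sess <- lapply(1:20, function(i)
    simulate_f2f_session(p0, session_id = paste0("Z", i), seed = 900 + i))
  iv <- split_by_kind(
    transitions_by_phase(bind_session_events(sess)))$exchange$interval
  fit <- fit_interval_mixture(iv, seed = 3)
  expect_lt(mixture_mass_below(fit, threshold = 0.5), 0.1)
})

test_that("the experiment design produces the full pair/session layout", {
  sessions <- simulate_experiment(seed = 2)
  expect_length(sessions, 60)
  pairs <- unique(vapply(sessions, function(s)
    paste(sort(c(s$subject, s$facing)), collapse = "-"), character(1)))
  expect_length(pairs, 15)
  per_pair <- table(vapply(sessions, function(s)
    paste(sort(c(s$subject, s$facing)), collapse = "-"), character(1)))
  expect_true(all(per_pair == 4))
  phases <- unique(bind_session_events(sessions)$phase)
  expect_setequal(phases, c("PRE", "F2F", "POST"))
  # every ordered (subject, facing) pair appears at least twice, so the
  # pseudo-pairing derangement is well defined
  ordered <- table(vapply(sessions, function(s)
    paste(s$subject, s$facing), character(1)))
  expect_true(all(ordered >= 2))
})

test_that("baseline_rate rescaling hits the requested rate", {
  p <- simulation_params(baseline_rate = 0.1)
  expect_equal(log10normal_mean(p$self_interval_log10_mean,
                                p$self_interval_log10_sd), 10,
               tolerance = 1e-9)
})
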