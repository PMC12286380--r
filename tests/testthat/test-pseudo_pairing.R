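# enumerate all derangements of 1:n by brute force (small n)
enumerate_derangements <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  Filter(function(p) all(p != seq_len(n)), perms(seq_len(n)))
}

test_that("a two-session pair is swapped, the only derangement", {
  s1 <- scripted_session("S1", c(1, 5, 9), c(2, 6))
  s2 <- scripted_session("S2", c(10, 20), c(11, 21, 31))
  ps <- make_pseudo_sessions(list(s1, s2), seed = 1)
  expect_length(ps, 2)
  src <- vapply(ps, function(p)
    c(p$source_subject_session, p$source_facing_session), character(2))
  expect_setequal(paste(src[1, ], src[2, ]), c("S1 S2", "S2 S1"))
  # subject track times are untouched, facing track comes from the other
  # session's facing bird
  p1 <- ps[[which(src[1, ] == "S1")]]
  expect_equal(p1$events$onset[p1$events$caller_id == "A"], c(1, 5, 9))
  expect_equal(p1$events$onset[p1$events$caller_id == "B"], c(11, 21, 31))
})

test_that("derangements are valid and uniform over the enumerated set", {
  all4 <- enumerate_derangements(4)
  expect_length(all4, 9) # subfactorial(4)
  keys <- character(0)
  for (s in 1:60) {
    d <- withr::with_seed(s, random_derangement(4))
    expect_true(all(d != 1:4))
    expect_setequal(d, 1:4)
    keys <- c(keys, paste(d, collapse = ""))
  }
  enum_keys <- vapply(all4, paste, character(1), collapse = "")
  expect_true(all(keys %in% enum_keys))
  # with 60 draws over 9 derangements every one should appear
  expect_setequal(unique(keys), enum_keys)
})

test_that("pseudo pairing conserves each bird's call-time multiset", {
  withr::local_seed(9)
  sess <- lapply(1:4, function(i) {
    scripted_session(paste0("S", i), sort(runif(15, 0, 880)),
                     sort(runif(12, 0, 880)))
  })
  ps <- make_pseudo_sessions(sess, seed = 3)
  orig_subj <- sort(unlist(lapply(sess, function(s)
    s$events$onset[s$events$caller_id == "A"])))
  pseudo_subj <- sort(unlist(lapply(ps, function(p)
    p$events$onset[p$events$caller_id == "A"])))
  expect_equal(pseudo_subj, orig_subj)
  orig_face <- sort(unlist(lapply(sess, function(s)
    s$events$onset[s$events$caller_id == "B"])))
  pseudo_face <- sort(unlist(lapply(ps, function(p)
    p$events$onset[p$events$caller_id == "B"])))
  expect_equal(pseudo_face, orig_face)
  # total call conservation
  expect_equal(sum(vapply(ps, function(p) nrow(p$events), integer(1))),
               sum(vapply(sess, function(s) nrow(s$events), integer(1))))
  # no pseudo session reuses its own facing track
  expect_true(all(vapply(ps, function(p)
    p$source_subject_session != p$source_facing_session, logical(1))))
})

test_that("a pair with a single session cannot be re-paired", {
  s1 <- scripted_session("S1", c(1, 2), c(3, 4))
  expect_error(make_pseudo_sessions(list(s1), seed = 1), "A B")
})

test_that("re-pairing destroys the short exchange mode of contagious calling", {
  p <- simulation_params(response_prob = 0.5)
  drops <- vapply(1:5, function(s) {
    sess <- lapply(1:4, function(i) {
      simulate_f2f_session(p, session_id = paste0("S", s, "_", i),
                           subject = "A", facing = "B",
                           seed = 5000 + 10 * s + i)
    })
    orig <- split_by_kind(
      transitions_by_phase(bind_session_events(sess)))$exchange$interval
    pseudo <- pseudo_transition_analysis(
      make_pseudo_sessions(sess, seed = s))$exchange_intervals
    # empirical short-latency mass must shrink under independence
    mean(pseudo < 0.5 & pseudo > 0) / mean(orig < 0.5 & orig > 0)
  }, numeric(1))
  expect_true(all(drops < 1))
  expect_lt(median(drops), 0.5)
})

test_that("an empty facing track leaves only repeated transitions", {
  s1 <- scripted_session("S1", c(1, 5, 9, 12), numeric(0))
  s2 <- scripted_session("S2", c(2, 6, 11), numeric(0))
  ps <- make_pseudo_sessions(list(s1, s2), seed = 2)
  ana <- pseudo_transition_analysis(ps)
  expect_length(ana$exchange_intervals, 0)
  expect_equal(length(ana$repeated_intervals), 5)
  expect_equal(ana$n_overlap, 0)
})
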