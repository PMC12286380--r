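test_that("calls are counted per subject, trial and phase", {
  ev <- validate_call_events(rbind(
    make_events(c(1, 2, 3), "A", phase = "PRE"),
    make_events(c(1, 2, 3, 4, 5), "A", phase = "F2F"),
    make_events(c(1.5, 2.5), "B", phase = "F2F"), # facing bird, not counted
    make_events(c(1, 2), "A", phase = "POST"),
    make_events(6, "A", phase = "F2F", vocal_type = "song") # not a call
  ))
  rows <- count_calls_by_phase(list(session_record("S1", "A", "B", ev)))
  expect_equal(rows$n_calls[rows$phase == "PRE"], 3)
  expect_equal(rows$n_calls[rows$phase == "F2F"], 5)
  expect_equal(rows$n_calls[rows$phase == "POST"], 2)

  empty <- session_record("S2", "A", "B",
                          make_events(numeric(0), character(0),
                                      session = "S2"))
  rows0 <- count_calls_by_phase(list(empty))
  expect_equal(rows0$n_calls, c(0, 0, 0))
})

test_that("the Poisson GLMM recovers a known phase effect and satisfies the AIC identity", {
  rows <- simulate_phase_counts(n_subjects = 6, n_trials = 10,
                                f2f_effect = log(1.5), subject_sd = 0.3,
                                seed = 21)
  fit <- fit_count_model(rows)
  expect_lt(abs(fit$fixed_effects[["phaseF2F"]] - log(1.5)), 0.15)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_parameters,
               tolerance = 1e-6)
  null <- fit_count_model(rows, include_phase = FALSE)
  expect_equal(null$aic, -2 * null$loglik + 2 * null$n_parameters,
               tolerance = 1e-6)
  expect_lt(fit$aic, null$aic)

  bad <- rows
  bad$n_calls[1] <- 2.5
  expect_error(fit_count_model(bad), "integer")
})

test_that("AIC prefers the null model for most replicates without a phase effect", {
  prefers_null <- vapply(1:30, function(s) {
    rows <- simulate_phase_counts(n_subjects = 4, n_trials = 6,
                                  f2f_effect = 0, seed = 300 + s)
    suppressWarnings({
      phase <- fit_count_model(rows)
      null <- fit_count_model(rows, include_phase = FALSE)
    })
    null$aic < phase$aic
  }, logical(1))
  expect_gte(mean(prefers_null), 0.7)
})

test_that("with no grouping variance the GLMM matches plain Poisson regression", {
  rows <- simulate_phase_counts(n_subjects = 4, n_trials = 8,
                                subject_sd = 0, trial_sd = 0, seed = 5)
  fit <- suppressWarnings(fit_count_model(rows))
  ref <- stats::glm(n_calls ~ factor(phase, levels = c("PRE", "F2F", "POST")),
                    family = stats::poisson(), data = rows)
  expect_equal(unname(fit$fixed_effects), unname(stats::coef(ref)),
               tolerance = 0.01)
})

test_that("scaling F2F counts raises the fitted F2F coefficient", {
  rows <- simulate_phase_counts(seed = 31)
  fit1 <- fit_count_model(rows)
  rows2 <- rows
  rows2$n_calls[rows2$phase == "F2F"] <- 2L * rows2$n_calls[rows2$phase == "F2F"]
  fit2 <- fit_count_model(rows2)
  expect_gt(fit2$fixed_effects[["phaseF2F"]], fit1$fixed_effects[["phaseF2F"]])
})

test_that("AIC model selection returns deltas and respects ties and data identity", {
  sel <- select_model_aic(c(phase = 4221.3, null = 4486.9))
  expect_equal(sel$best_index, 1)
  expect_equal(sel$delta_table$delta_aic, c(0, 265.6), tolerance = 1e-9)

  single <- select_model_aic(c(only = 123.4))
  expect_equal(single$delta_table$delta_aic, 0)
  expect_false(single$tie)

  tied <- select_model_aic(c(a = 10, b = 10))
  expect_equal(tied$best_index, 1)
  expect_true(tied$tie)

  rows_a <- simulate_phase_counts(n_subjects = 3, n_trials = 3, seed = 1)
  rows_b <- simulate_phase_counts(n_subjects = 3, n_trials = 3, seed = 2)
  fit_a <- suppressWarnings(fit_count_model(rows_a))
  fit_b <- suppressWarnings(fit_count_model(rows_b))
  expect_error(select_model_aic(list(fit_a, fit_b)), "identical data")
})
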