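# Per-phase call counts and Poisson mixed-effects modelling.
#
# The question: does a subject bird call more when it can see and hear its
# partner (F2F) than when alone (PRE/POST)? Counts per (subject, trial,
# phase) are modelled with a Poisson log-link GLMM with random intercepts
# for subject and trial; the phase model is compared against an
# intercept-only null by AIC.

#' Count a subject's calls per phase
#'
#' One row per (subject, trial, phase) counting the subject's `"call"`
#' events. The facing bird's F2F calls are not counted toward the subject's
#' row. Trial is the session identity.
#'
#' @param sessions List of `session_record` objects.
#' @return A tibble with columns subject_id, trial_id, phase, n_calls;
#'   phases with no events yield 0.
#' @export
count_calls_by_phase <- function(sessions) {
  dplyr::bind_rows(lapply(sessions, function(s) {
    ev <- s$events
    n <- vapply(PHASE_LEVELS, function(ph) {
      sum(ev$phase == ph & ev$caller_id == s$subject &
            ev$vocal_type == "call")
    }, integer(1))
    tibble::tibble(subject_id = s$subject, trial_id = s$session_id,
                   phase = PHASE_LEVELS, n_calls = unname(n))
  }))
}

#' Fit the Poisson count model
#'
#' Poisson GLMM (log link) for call counts with independent Gaussian random
#' intercepts for subject and trial, fitted by Laplace-approximated maximum
#' likelihood via [lme4::glmer()]. Phase enters as a fixed effect with PRE
#' as the reference level, so the F2F and POST coefficients are log rate
#' ratios versus PRE; with `include_phase = FALSE` the fixed part is an
#' intercept only (the null model).
#'
#' @param rows Count table from [count_calls_by_phase()].
#' @param include_phase Include the phase fixed effect? (default TRUE)
#' @return A `count_model_fit`: `fixed_effects`,
#'   `random_intercept_variances` (subject, trial), `loglik`, `aic`,
#'   `n_parameters`, `singular` flag, and the underlying `model`.
#' @export
fit_count_model <- function(rows, include_phase = TRUE) {
  if (any(rows$n_calls < 0) || any(rows$n_calls != round(rows$n_calls))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(unique(rows$subject_id)) < 2 ||
      length(unique(rows$trial_id)) < 2) {
    stop("need at least 2 subjects and 2 trials to fit random intercepts",
         call. = FALSE)
  }
  dat <- data.frame(
    n_calls = as.integer(rows$n_calls),
    phase = factor(rows$phase, levels = PHASE_LEVELS),
    subject_id = factor(rows$subject_id),
    trial_id = factor(rows$trial_id)
  )
  form <- if (include_phase) {
    n_calls ~ phase + (1 | subject_id) + (1 | trial_id)
  } else {
    n_calls ~ 1 + (1 | subject_id) + (1 | trial_id)
  }
  model <- suppressMessages(
    lme4::glmer(form, data = dat, family = stats::poisson(link = "log"))
  )
  singular <- lme4::isSingular(model)
  if (singular) {
    warning("singular fit: a random-intercept variance is (near) zero",
            call. = FALSE)
  }
  ll <- logLik(model)
  vc <- lme4::VarCorr(model)
  structure(
    list(
      fixed_effects = lme4::fixef(model),
      random_intercept_variances = c(
        subject = as.numeric(vc$subject_id),
        trial = as.numeric(vc$trial_id)
      ),
      loglik = as.numeric(ll),
      aic = AIC(model),
      n_parameters = attr(ll, "df"),
      include_phase = include_phase,
      singular = singular,
      n_rows = nrow(dat),
      data_digest = digest_rows(rows),
      model = model
    ),
    class = "count_model_fit"
  )
}

# cheap fingerprint of a count table, to refuse AIC comparisons across
# different data
digest_rows <- function(rows) {
  rows <- rows[order(rows$subject_id, rows$trial_id, rows$phase), ]
  paste(nrow(rows), sum(rows$n_calls),
        paste(utils::head(rows$n_calls, 50), collapse = ","))
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat("<count_model_fit> Poisson GLMM,",
      if (x$include_phase) "phase model" else "null model", "\n")
  cat("  fixed effects (log link):\n")
  print(round(x$fixed_effects, 4))
  cat("  random-intercept variances: subject",
      round(x$random_intercept_variances[["subject"]], 4), ", trial",
      round(x$random_intercept_variances[["trial"]], 4), "\n")
  cat(sprintf("  loglik %.2f, AIC %.1f (%d parameters)%s\n", x$loglik,
              x$aic, x$n_parameters,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Select the best count model by AIC
#'
#' @param fits List of `count_model_fit` objects fitted on identical rows
#'   (or a numeric vector of AIC values for a bare comparison).
#' @return A list with `best` (the minimum-AIC fit, first by input order on
#'   ties), `delta_table` (model, aic, delta_aic) and `tie` flag.
#' @export
select_model_aic <- function(fits) {
  if (is.numeric(fits)) {
    labels <- if (!is.null(names(fits))) names(fits) else
      paste0("model", seq_along(fits))
    aics <- unname(fits)
    fits <- as.list(aics)
  } else {
    digests <- vapply(fits, function(f) f$data_digest, character(1))
    if (length(unique(digests)) > 1) {
      stop("AIC comparison requires fits on identical data", call. = FALSE)
    }
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    labels <- vapply(fits, function(f) {
      if (f$include_phase) "phase" else "null"
    }, character(1))
  }
  best_i <- which.min(aics) # which.min takes the first on ties
  tie <- sum(aics == aics[best_i]) > 1
  list(
    best = fits[[best_i]],
    best_index = best_i,
    delta_table = tibble::tibble(model = labels, aic = aics,
                                 delta_aic = aics - aics[best_i]),
    tie = tie
  )
}
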