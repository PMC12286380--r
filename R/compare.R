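# Parametric Monte-Carlo comparison of two fitted mixture components.
#
# Per repetition one value is drawn from each component's estimated normal
# distribution and the difference recorded; the comparison is summarized by
# the central percentile interval of the 10,000 differences and whether it
# contains zero. Although often described as a permutation test, the
# procedure is parametric Monte Carlo from the fitted normals; no p-value
# is computed.

#' Percentile interval of differences between two fitted normals
#'
#' Draws one value from `N(mean_a, var_a)` and one from `N(mean_b, var_b)`
#' per repetition, records `a - b`, and returns the central
#' `level`-percent empirical percentile interval of the differences
#' (2.5th/97.5th percentiles at the default level), with a contains-zero
#' verdict. Deterministic given `seed`.
#'
#' @param mean_a,var_a Mean and variance (not SD) of the first component.
#' @param mean_b,var_b Mean and variance of the second component.
#' @param n_reps Number of repetitions (>= 100; default 10000).
#' @param level Central percentile level in percent (default 95).
#' @param seed Integer seed.
#' @param order Text recording the difference direction (default "A - B");
#'   kept because the sign convention matters when matching bounds across
#'   comparisons.
#' @return A `percentile_interval` object with `lower`, `upper`, `level`,
#'   `n_reps`, `contains_zero`, `order`, `seed`.
#' @export
difference_percentile_interval <- function(mean_a, var_a, mean_b, var_b,
                                           n_reps = 10000L, level = 95,
                                           seed = 1L, order = "A - B") {
  if (var_a <= 0 || var_b <= 0) {
    stop("component variances must be positive", call. = FALSE)
  }
  stopifnot(n_reps >= 100, level > 0, level < 100)
  diffs <- withr::with_seed(as.integer(seed), {
    rnorm(n_reps, mean_a, sqrt(var_a)) - rnorm(n_reps, mean_b, sqrt(var_b))
  })
  alpha <- (100 - level) / 200
  # type 7: linear interpolation between order statistics
  bounds <- unname(quantile(diffs, probs = c(alpha, 1 - alpha), type = 7))
  structure(
    list(lower = bounds[1], upper = bounds[2], level = level,
         n_reps = as.integer(n_reps),
         contains_zero = bounds[1] <= 0 && 0 <= bounds[2],
         order = order, seed = as.integer(seed)),
    class = "percentile_interval"
  )
}

#' Compare a fitted component between two conditions
#'
#' Extracts the named component's mean and variance from each converged fit
#' and delegates to [difference_percentile_interval()]; the difference is
#' taken as `fit_a - fit_b`.
#'
#' @param fit_a,fit_b Converged `gmm_fit` objects.
#' @param component `"short"` or `"long"`.
#' @param n_reps,level,seed Passed to [difference_percentile_interval()].
#' @param labels Length-2 character vector naming the two conditions, used
#'   to record the difference direction.
#' @return A `percentile_interval`.
#' @export
compare_conditions <- function(fit_a, fit_b, component = c("short", "long"),
                               n_reps = 10000L, level = 95, seed = 1L,
                               labels = c("A", "B")) {
  component <- match.arg(component)
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both mixture fits must have converged", call. = FALSE)
  }
  difference_percentile_interval(
    mean_a = fit_a$mean[[component]], var_a = fit_a$variance[[component]],
    mean_b = fit_b$mean[[component]], var_b = fit_b$variance[[component]],
    n_reps = n_reps, level = level, seed = seed,
    order = paste(labels[1], "-", labels[2])
  )
}

#' @export
print.percentile_interval <- function(x, digits = 3, ...) {
  cat(sprintf(
    "%gth percentile range: [%.*f, %.*f]; contains zero: %s; order: %s; n_reps = %d; seed = %d\n",
    x$level, digits, x$lower, digits, x$upper,
    if (x$contains_zero) "yes" else "no", x$order, x$n_reps, x$seed))
  invisible(x)
}
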