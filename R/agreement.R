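# Inter-annotator validation: agreement rate between two independent label
# sets over the same recording, and a bias check on onset/offset time
# differences (a one-sample t interval on the nearest-neighbour deltas).

#' Agreement (accuracy) rate
#'
#' `accuracy = n_agree / n_all`, the fraction of segmented vocal regions on
#' which two annotators agree on both vocal-type class and caller.
#'
#' @param n_agree Number of agreements (0 <= n_agree <= n_all).
#' @param n_all Total number of segmented regions (> 0).
#' @return The accuracy as a proportion in `[0, 1]`.
#' @export
agreement_accuracy <- function(n_agree, n_all) {
  if (n_all <= 0) stop("n_all must be positive", call. = FALSE)
  stopifnot(n_agree >= 0, n_agree <= n_all)
  n_agree / n_all
}

#' Nearest-neighbour time differences
#'
#' For each time in `times_a`, the signed difference to the nearest time in
#' `times_b` (`a - nearest_b`). Exact distance ties resolve to the earlier
#' neighbour.
#'
#' @param times_a,times_b Non-empty numeric vectors of times in seconds.
#' @return Numeric vector of deltas, one per element of `times_a`.
#' @export
nearest_neighbor_deltas <- function(times_a, times_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both time lists must be non-empty", call. = FALSE)
  }
  b <- sort(times_b)
  vapply(times_a, function(t) {
    d <- abs(t - b)
    # ties to the earlier neighbour: which.min picks the first (sorted) hit
    t - b[which.min(d)]
  }, numeric(1))
}

#' One-sample t confidence interval for a mean delta
#'
#' Student-t interval for the mean of the deltas; a bias between annotators
#' shows as an interval excluding zero. Constant deltas (zero variance)
#' yield the degenerate zero-width interval at the common value.
#'
#' @param deltas Numeric vector, length >= 2.
#' @param level Confidence level in percent (default 95).
#' @return Numeric vector `c(lower, upper)` with attribute
#'   `"excludes_zero"`.
#' @export
one_sample_mean_ci <- function(deltas, level = 95) {
  if (length(deltas) < 2) {
    stop("need at least 2 deltas for a t interval", call. = FALSE)
  }
  stopifnot(level > 0, level < 100)
  if (sd(deltas) == 0) {
    ci <- c(deltas[1], deltas[1])
  } else {
    ci <- as.numeric(
      t.test(deltas, conf.level = level / 100)$conf.int
    )
  }
  structure(ci, excludes_zero = !(ci[1] <= 0 && 0 <= ci[2]))
}

#' Match two annotators' segments and score agreement
#'
#' Greedy nearest-onset matching: candidate pairs are considered in order
#' of increasing onset difference and accepted while within `window`
#' seconds, each segment used at most once. A matched pair agrees when both
#' vocal type and caller are identical; unmatched segments on either side
#' count as disagreements, so `n_all` is the number of distinct segmented
#' regions (matched pairs plus unmatched segments on both sides).
#'
#' @param events_a,events_b `call_events` tibbles from the two annotators
#'   covering the same recording.
#' @param window Maximum onset difference for a match, seconds
#'   (default 0.5).
#' @param level Confidence level in percent for the bias intervals.
#' @return An `agreement_result`: `n_all`, `n_agree`, `accuracy`,
#'   `onset_deltas`, `offset_deltas`, `onset_delta_ci`, `offset_delta_ci`.
#' @export
match_annotations <- function(events_a, events_b, window = 0.5,
                              level = 95) {
  na <- nrow(events_a)
  nb <- nrow(events_b)
  if (na == 0 || nb == 0) {
    stop("both annotators must contribute at least one segment",
         call. = FALSE)
  }
  cand <- expand.grid(i = seq_len(na), j = seq_len(nb))
  cand$d <- abs(events_a$onset[cand$i] - events_b$onset[cand$j])
  cand <- cand[cand$d <= window, ]
  cand <- cand[order(cand$d), ]
  used_a <- logical(na)
  used_b <- logical(nb)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  n_matched <- nrow(pairs)
  n_all <- n_matched + sum(!used_a) + sum(!used_b)
  agree <- if (n_matched > 0) {
    events_a$vocal_type[pairs[, 1]] == events_b$vocal_type[pairs[, 2]] &
      events_a$caller_id[pairs[, 1]] == events_b$caller_id[pairs[, 2]]
  } else {
    logical(0)
  }
  onset_deltas <- events_a$onset[pairs[, 1]] - events_b$onset[pairs[, 2]]
  offset_deltas <- events_a$offset[pairs[, 1]] - events_b$offset[pairs[, 2]]
  structure(
    list(
      n_all = n_all,
      n_agree = sum(agree),
      accuracy = agreement_accuracy(sum(agree), n_all),
      onset_deltas = onset_deltas,
      offset_deltas = offset_deltas,
      onset_delta_ci = if (length(onset_deltas) >= 2)
        one_sample_mean_ci(onset_deltas, level) else NULL,
      offset_delta_ci = if (length(offset_deltas) >= 2)
        one_sample_mean_ci(offset_deltas, level) else NULL
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> accuracy %.2f%% (%d/%d)\n",
              100 * x$accuracy, x$n_agree, x$n_all))
  fmt_ci <- function(ci, label) {
    if (is.null(ci)) return()
    cat(sprintf("  %s delta CI: [%.3f, %.3f] s; bias: %s\n", label, ci[1],
                ci[2], if (attr(ci, "excludes_zero")) "yes" else "no"))
  }
  fmt_ci(x$onset_delta_ci, "onset")
  fmt_ci(x$offset_delta_ci, "offset")
  invisible(x)
}
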