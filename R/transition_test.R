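## Randomization test linking fitted break points to the anatomical
## transition point: for each specimen, is the nearest fitted break closer to
## the transition point than randomly placed breaks would be, and across
## specimens, are more of them closer than a fair coin predicts?

#' Distance from the transition point to the nearest break point
#'
#' @param breakpoints Numeric vector of break positions (>= 1 of them).
#' @param transition_point Vertebra number of the transition point.
#' @return `min(abs(breakpoints - transition_point))`, in vertebra units.
#' @examples
#' nearest_break_distance(c(12, 45.8), 12)  # 0
#' @export
nearest_break_distance <- function(breakpoints, transition_point) {
  if (length(breakpoints) < 1 || anyNA(breakpoints)) {
    stop_caudseg("at least one break point required", "caudseg_validation_error")
  }
  if (is.na(transition_point)) {
    stop_caudseg("transition point unknown", "caudseg_validation_error")
  }
  min(abs(breakpoints - transition_point))
}

# admissible interior integer positions for randomized break placement
.admissible_positions <- function(n_vertebrae) seq(2L, n_vertebrae - 1L)

#' Mean nearest-break distance under random break placement
#'
#' Monte-Carlo null for one specimen: in each of `reps` randomizations,
#' `n_breaks` break positions are placed uniformly without replacement on the
#' interior integer positions `2..(n_vertebrae - 1)`, and the distance from
#' the transition point to the nearest of them is recorded; the mean over
#' randomizations is returned.
#'
#' @param n_vertebrae Number of vertebrae in the series (largest position).
#' @param n_breaks Number of break points to place (>= 1).
#' @param transition_point Transition vertebra, in `1..n_vertebrae`.
#' @param reps Number of randomizations (default 1000).
#' @param seed Optional integer seed.
#' @return Mean nearest-break distance (vertebra units).
#' @seealso [expected_null_distance()] for the exact expectation.
#' @export
null_mean_distance <- function(n_vertebrae, n_breaks, transition_point,
                               reps = 1000, seed = NULL) {
  n_breaks <- as.integer(n_breaks)
  if (n_breaks < 1) stop_caudseg("n_breaks must be >= 1", "caudseg_validation_error")
  if (transition_point < 1 || transition_point > n_vertebrae) {
    stop_caudseg("transition point outside 1..n_vertebrae", "caudseg_validation_error")
  }
  pos <- .admissible_positions(n_vertebrae)
  if (n_breaks > length(pos)) {
    stop_caudseg("more break points than admissible interior positions",
                 "caudseg_validation_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- abs(pos - transition_point)
  if (n_breaks == 1L) {
    draws <- d[sample.int(length(pos), reps, replace = TRUE)]
    return(mean(draws))
  }
  total <- 0
  for (r in seq_len(reps)) {
    total <- total + min(d[sample.int(length(pos), n_breaks)])
  }
  total / reps
}

#' Exact expected nearest-break distance under random placement
#'
#' Closed-form counterpart of [null_mean_distance()], by summing the survival
#' function of the (integer-valued) nearest distance: `P(D > d)` equals the
#' probability that all `n_breaks` sampled positions avoid the window of
#' admissible positions within `d` of the transition point.
#'
#' @inheritParams null_mean_distance
#' @return The exact expectation of the nearest-break distance.
#' @export
expected_null_distance <- function(n_vertebrae, n_breaks, transition_point) {
  pos <- .admissible_positions(n_vertebrae)
  m <- length(pos)
  n_breaks <- as.integer(n_breaks)
  if (n_breaks < 1 || n_breaks > m) {
    stop_caudseg("n_breaks outside 1..#admissible positions", "caudseg_validation_error")
  }
  d <- abs(pos - transition_point)
  dmax <- max(d)
  ev <- 0
  for (dd in 0:(dmax - 1)) {
    within <- sum(d <= dd)
    ev <- ev + exp(lchoose(m - within, n_breaks) - lchoose(m, n_breaks))
  }
  ev
}

#' Two-sided exact binomial p-value against a fair coin
#'
#' `p = 2 * min(P(X <= k), P(X >= k))`, truncated at 1, for
#' `X ~ Binomial(n, 1/2)`. With the symmetric null this equals the classical
#' exact binomial test.
#'
#' @param k Observed success count.
#' @param n Number of trials.
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' proximity_binomial_p(18, 25)  # 0.0433
#' @export
proximity_binomial_p <- function(k, n) {
  stopifnot(k >= 0, k <= n, n >= 1)
  min(1, 2 * min(pbinom(k, n, 0.5), pbinom(k - 1, n, 0.5, lower.tail = FALSE)))
}

#' Randomization test of break-point / transition-point proximity
#'
#' For every eligible specimen (chosen model segmented or discontinuous, so
#' at least one break, and transition point known), compares the actual
#' nearest-break distance with the mean distance under [null_mean_distance()]
#' randomizations that preserve the specimen's fitted break count and series
#' length. The number of specimens whose actual distance is strictly lower
#' than their null mean is then referred to a two-sided exact binomial test
#' against 0.5. Specimens whose chosen model is linear, or lacking a
#' transition point, are excluded and listed.
#'
#' @param results List of `model_selection_result` (e.g. from
#'   [screen_batch()]); failures and ineligible specimens are skipped.
#' @param reps Randomizations per specimen (default 1000).
#' @param seed Master seed; per-specimen randomization seeds are derived by a
#'   stable hash of the specimen id.
#' @return An object of class `proximity_test_result`: `per_specimen` data
#'   frame (`specimen_id`, `n_vertebrae`, `n_breaks`, `actual_distance`,
#'   `null_mean_distance`, `closer`), `n_closer`, `n_total`, `binomial_p`,
#'   `excluded` (character vector of specimen ids).
#' @export
proximity_test <- function(results, reps = 1000, seed = NULL) {
  stopifnot(is.list(results))
  excluded <- character()
  rows <- list()
  for (r in results) {
    if (inherits(r, "model_selection_failure")) {
      excluded <- c(excluded, r$specimen_id)
      next
    }
    stopifnot(inherits(r, "model_selection_result"))
    bp <- chosen_breakpoints(r)
    if (length(bp) < 1 || is.na(r$transition_point)) {
      excluded <- c(excluded, r$specimen_id)
      next
    }
    actual <- nearest_break_distance(bp, r$transition_point)
    sub_seed <- if (!is.null(seed)) stable_seed(seed, r$specimen_id, "null") else NULL
    nm <- null_mean_distance(r$n_vertebrae, length(bp), r$transition_point,
                             reps = reps, seed = sub_seed)
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = r$specimen_id, n_vertebrae = r$n_vertebrae,
      n_breaks = length(bp), actual_distance = actual,
      null_mean_distance = nm, closer = actual < nm,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    stop_caudseg("no specimen eligible for the proximity test (need >= 1 break and a transition point)",
                 "caudseg_validation_error")
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  n_total <- nrow(per)
  n_closer <- sum(per$closer)
  structure(list(
    per_specimen = per,
    n_closer = n_closer,
    n_total = n_total,
    binomial_p = proximity_binomial_p(n_closer, n_total),
    excluded = excluded
  ), class = "proximity_test_result")
}

#' @export
print.proximity_test_result <- function(x, ...) {
  cat(sprintf("<proximity_test_result> %d of %d specimens closer than chance (exact binomial p = %.4g)\n",
              x$n_closer, x$n_total, x$binomial_p))
  if (length(x$excluded)) {
    cat("  excluded (no break or no transition point):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
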