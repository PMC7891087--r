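## Per-specimen orchestration: Davies gate, segmented candidates with 1-4
## breaks, AIC choice, optional discontinuous comparison, and congruence
## assessment between replicate fits.

# Deterministic 32-bit seed from a master seed and arbitrary string tokens,
# so per-candidate seeds do not depend on batch order.
stable_seed <- function(master_seed, ...) {
  tokens <- paste(c(...), collapse = "\x1f")
  h <- (as.numeric(master_seed) %% 2147483647) + 1
  for (ch in utf8ToInt(tokens)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Select the best break-point model for one caudal series
#'
#' Runs the per-specimen inference chain: a [davies_test()] gate at level
#' `alpha`; if the gate passes, segmented candidates with 1 to `max_breaks`
#' break points (fitted along the chained path of [fit_segmented_path()],
#' unfittable candidates discarded and recorded) compete on AIC, ties going
#' to fewer breaks; if the gate fails the model is linear, unless
#' `allow_discontinuous` and the discontinuous two-regime model beats the
#' linear AIC. The linear model does not compete once the gate has passed.
#'
#' @param series A [caudal_series].
#' @param max_breaks Maximum break count (default 4).
#' @param alpha Gate significance level (default 0.05).
#' @param allow_discontinuous Offer the two-regime model when the gate fails
#'   (default `FALSE`; the discontinuous model is opt-in per specimen).
#' @param seed Master seed; per-candidate seeds are derived by a stable hash
#'   of `(specimen_id, n_breaks)` so batch results are order-independent.
#' @param n_boot,max_iter,davies_k Fitting controls, see [fit_segmented()]
#'   and [davies_test()].
#' @return An object of class `model_selection_result`: `specimen_id`,
#'   `davies`, `linear` fit, `candidates` (named numeric vector of AICs,
#'   `NA` where unfittable), `discontinuous_aic`, `chosen` (`"linear"`,
#'   `"segmented"` or `"discontinuous"`), `chosen_n_breaks`, `chosen_fit`,
#'   `n_vertebrae`, `transition_point`, `warning_flags`.
#' @export
select_model <- function(series, max_breaks = 4, alpha = 0.05,
                         allow_discontinuous = FALSE, seed = NULL,
                         n_boot = 50, max_iter = 10, davies_k = 10) {
  stopifnot(inherits(series, "caudal_series"))
  x <- series$positions; y <- series$lengths
  if (length(x) < 5) {
    stop_caudseg(sprintf("series '%s' has fewer than 5 vertebrae", series$specimen_id),
                 "caudseg_validation_error")
  }
  dv <- davies_test(x, y, k = davies_k)
  lin <- fit_linear(x, y)
  warn <- character()
  candidates <- setNames(rep(NA_real_, max_breaks), paste0("breaks_", seq_len(max_breaks)))
  disc_aic <- NA_real_
  chosen <- "linear"; chosen_fit <- lin; chosen_n_breaks <- 0L

  if (!dv$degenerate && dv$p_value < alpha) {
    seeds <- if (!is.null(seed)) {
      vapply(seq_len(max_breaks), function(k)
        stable_seed(seed, series$specimen_id, k), integer(1))
    } else NULL
    fits <- fit_segmented_path(x, y, max_breaks = max_breaks, n_boot = n_boot,
                               max_iter = max_iter, seeds = seeds)
    fitted_ok <- !vapply(fits, is.null, logical(1))
    candidates[fitted_ok] <- vapply(fits[fitted_ok], function(f) f$aic, numeric(1))
    if (any(!fitted_ok)) {
      warn <- c(warn, sprintf("candidate(s) with %s break(s) unfittable",
                              paste(which(!fitted_ok), collapse = ", ")))
    }
    if (any(fitted_ok)) {
      # minimal AIC; which.min returns the first minimum, i.e. fewest breaks
      best_k <- which.min(candidates)
      chosen <- "segmented"
      chosen_fit <- fits[[best_k]]
      chosen_n_breaks <- as.integer(best_k)
    } else {
      warn <- c(warn, "gate passed but all segmented candidates unfittable; falling back to linear")
    }
  } else if (allow_discontinuous) {
    disc <- tryCatch(fit_discontinuous(x, y), caudseg_error = function(e) NULL)
    if (!is.null(disc)) {
      disc_aic <- disc$aic
      if (disc$aic < lin$aic) {
        chosen <- "discontinuous"
        chosen_fit <- disc
        chosen_n_breaks <- 1L
      }
    }
  }

  structure(list(
    specimen_id = series$specimen_id,
    taxon = series$taxon,
    davies = dv,
    linear = lin,
    candidates = candidates,
    discontinuous_aic = disc_aic,
    chosen = chosen,
    chosen_n_breaks = chosen_n_breaks,
    chosen_fit = chosen_fit,
    n_vertebrae = max(x),
    transition_point = series$transition_point,
    warning_flags = warn
  ), class = "model_selection_result")
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat(sprintf("<model_selection_result> %s: chosen = %s%s (Davies p = %.4g)\n",
              x$specimen_id, x$chosen,
              if (x$chosen == "segmented") sprintf("(%d)", x$chosen_n_breaks) else "",
              x$davies$p_value))
  aics <- c(linear = x$linear$aic, x$candidates,
            discontinuous = x$discontinuous_aic)
  aics <- aics[!is.na(aics)]
  cat("  AIC:", paste(sprintf("%s = %.1f", names(aics), aics), collapse = ", "), "\n")
  for (w in x$warning_flags) cat("  warning:", w, "\n")
  invisible(x)
}

#' Break points of the chosen model
#'
#' @param result A `model_selection_result`.
#' @return Numeric vector of break positions: the fitted break points for a
#'   segmented choice, the split position for a discontinuous choice, and
#'   `numeric(0)` for a linear choice.
#' @export
chosen_breakpoints <- function(result) {
  stopifnot(inherits(result, "model_selection_result"))
  switch(result$chosen,
    segmented = result$chosen_fit$breakpoints,
    discontinuous = result$chosen_fit$split_position,
    numeric(0)
  )
}

#' Congruence between two sets of fitted break points
#'
#' Pairs the break points of two converged segmented fits (by order when the
#' break counts agree, otherwise by nearest position, flagged) and reports,
#' per pair, the absolute distance and whether the second fit's break point
#' lies within `z` standard errors of the first fit's.
#'
#' @param fit_a,fit_b Converged `segmented_fit` objects; `fit_a` supplies the
#'   standard errors used for the encompassment check.
#' @param z Half-width of the encompassment band in SE units (default 1).
#' @return An object of class `breakpoint_congruence`: a data frame `pairs`
#'   (`psi_a`, `se_a`, `psi_b`, `distance`, `encompassed`), the
#'   `fraction_encompassed`, and a `mismatch` flag for unequal break counts.
#' @export
compare_breakpoint_sets <- function(fit_a, fit_b, z = 1) {
  stopifnot(inherits(fit_a, "segmented_fit"), inherits(fit_b, "segmented_fit"))
  if (!fit_a$converged || !fit_b$converged) {
    stop_caudseg("both fits must have converged", "caudseg_validation_error")
  }
  pa <- fit_a$breakpoints; sa <- fit_a$breakpoint_se
  pb <- fit_b$breakpoints
  mismatch <- length(pa) != length(pb)
  if (!mismatch) {
    idx <- seq_along(pa)
  } else {
    # pair each of fit_b's break points with the nearest of fit_a's
    idx <- vapply(pb, function(p) which.min(abs(pa - p)), integer(1))
  }
  pairs <- data.frame(
    psi_a = pa[idx], se_a = sa[idx], psi_b = pb,
    distance = abs(pa[idx] - pb)
  )
  pairs$encompassed <- pairs$distance <= z * pairs$se_a
  structure(list(
    pairs = pairs,
    fraction_encompassed = mean(pairs$encompassed),
    mismatch = mismatch,
    z = z
  ), class = "breakpoint_congruence")
}

#' @export
print.breakpoint_congruence <- function(x, ...) {
  cat(sprintf("<breakpoint_congruence> %d pair(s), %.0f%% encompassed at +/- %g SE%s\n",
              nrow(x$pairs), 100 * x$fraction_encompassed, x$z,
              if (x$mismatch) " (break counts differ; paired by proximity)" else ""))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Run model selection over a batch of series
#'
#' Applies [select_model()] independently to each series. Per-specimen
#' failures are isolated: a failing specimen yields an entry of class
#' `model_selection_failure` carrying the error message, and the batch
#' continues. Results are deterministic under the master seed and independent
#' of batch order (per-candidate seeds are hashed from specimen ids).
#'
#' @param series A list of [caudal_series].
#' @param ... Passed to [select_model()] (e.g. `alpha`, `max_breaks`, `seed`,
#'   `allow_discontinuous`).
#' @return A named list, one element per series, order preserved.
#' @export
screen_batch <- function(series, ...) {
  stopifnot(is.list(series), length(series) >= 1)
  out <- lapply(series, function(s) {
    tryCatch(select_model(s, ...), error = function(e) {
      structure(list(specimen_id = s$specimen_id, message = conditionMessage(e)),
                class = "model_selection_failure")
    })
  })
  names(out) <- vapply(series, function(s) s$specimen_id, character(1))
  out
}

#' Summarise a batch of model-selection results as a data frame
#'
#' @param results List returned by [screen_batch()].
#' @return A data frame with one row per specimen: `specimen_id`, `davies_p`,
#'   `chosen`, `n_breaks`, `breakpoints` and `breakpoint_se`
#'   (slash-separated), `aic_linear`, `aic_chosen`, `failed`.
#' @export
selection_summary <- function(results) {
  rows <- lapply(results, function(r) {
    if (inherits(r, "model_selection_failure")) {
      return(data.frame(specimen_id = r$specimen_id, davies_p = NA_real_,
                        chosen = NA_character_, n_breaks = NA_integer_,
                        breakpoints = "", breakpoint_se = "",
                        aic_linear = NA_real_, aic_chosen = NA_real_,
                        failed = TRUE, stringsAsFactors = FALSE))
    }
    bp <- chosen_breakpoints(r)
    se <- if (r$chosen == "segmented") r$chosen_fit$breakpoint_se else numeric(0)
    data.frame(
      specimen_id = r$specimen_id, davies_p = r$davies$p_value,
      chosen = r$chosen, n_breaks = r$chosen_n_breaks,
      breakpoints = paste(sprintf("%.3f", bp), collapse = "/"),
      breakpoint_se = paste(sprintf("%.3f", se), collapse = "/"),
      aic_linear = r$linear$aic,
      aic_chosen = if (!is.null(r$chosen_fit$aic)) r$chosen_fit$aic else NA_real_,
      failed = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
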