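## Reporting drivers: run configuration, per-specimen fit reports, and the
## end-to-end study report (batch model selection -> proximity test ->
## allometry), serialisable to JSON. A thin command-line wrapper around these
## functions is installed at inst/cli/caudseg.

#' Assemble a run configuration
#'
#' Collects the tunable constants of the pipeline: the Davies gate level, the
#' break-count ceiling, bootstrap restarts and iteration cap of the segmented
#' fitter, the Davies grid size, the number of randomizations of the
#' proximity test, the master seed, and the allometric interval type.
#'
#' @param alpha Davies gate level (default 0.05).
#' @param max_breaks Maximum break count (default 4).
#' @param n_boot Bootstrap restarts per segmented candidate (default 50).
#' @param max_iter Iteration cap per start (default 10).
#' @param davies_k Davies grid size (default 10).
#' @param reps Randomizations per specimen in the proximity test
#'   (default 1000).
#' @param seed Master seed (default 1).
#' @param interval_type `"prediction"` or `"confidence"` for
#'   [predict_interval()].
#' @param allow_discontinuous Offer the two-regime model where the Davies
#'   gate fails (default `FALSE`).
#' @return A named list with class `run_config`.
#' @export
run_config <- function(alpha = 0.05, max_breaks = 4, n_boot = 50, max_iter = 10,
                       davies_k = 10, reps = 1000, seed = 1,
                       interval_type = c("prediction", "confidence"),
                       allow_discontinuous = FALSE) {
  interval_type <- match.arg(interval_type)
  if (alpha <= 0 || alpha >= 1) {
    stop_caudseg("alpha must be in (0, 1)", "caudseg_validation_error")
  }
  counts <- c(max_breaks = max_breaks, n_boot = n_boot, max_iter = max_iter,
              davies_k = davies_k, reps = reps)
  if (any(counts < 1)) {
    stop_caudseg("all counts must be positive", "caudseg_validation_error")
  }
  structure(list(
    alpha = alpha, max_breaks = as.integer(max_breaks),
    n_boot = as.integer(n_boot), max_iter = as.integer(max_iter),
    davies_k = as.integer(davies_k), reps = as.integer(reps),
    seed = as.integer(seed), interval_type = interval_type,
    allow_discontinuous = isTRUE(allow_discontinuous)
  ), class = "run_config")
}

# strip non-serialisable pieces of a fit for the JSON report
.fit_report <- function(fit) {
  if (inherits(fit, "segmented_fit")) {
    list(model = "segmented", n_breaks = fit$n_breaks,
         breakpoints = fit$breakpoints, breakpoint_se = fit$breakpoint_se,
         intercept = fit$intercept, base_slope = fit$base_slope,
         slope_changes = fit$slope_changes, rss = fit$rss, aic = fit$aic,
         converged = fit$converged, n_iterations = fit$n_iterations)
  } else if (inherits(fit, "discontinuous_fit")) {
    list(model = "discontinuous", split_position = fit$split_position,
         intercepts = fit$intercepts, slopes = fit$slopes,
         rss = fit$rss, aic = fit$aic)
  } else {
    list(model = "linear", intercept = fit$intercept, slope = fit$slope,
         rss = fit$rss, aic = fit$aic)
  }
}

.selection_report <- function(r) {
  list(
    specimen_id = r$specimen_id,
    davies = list(p_value = r$davies$p_value, max_stat = r$davies$max_stat,
                  best_theta = r$davies$best_theta),
    aic = list(linear = r$linear$aic,
               candidates = as.list(r$candidates),
               discontinuous = r$discontinuous_aic),
    chosen = r$chosen,
    fit = .fit_report(r$chosen_fit),
    n_vertebrae = r$n_vertebrae,
    transition_point = r$transition_point,
    warnings = r$warning_flags
  )
}

.provenance <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

#' Fit and report one specimen from a series file
#'
#' Reads the series table, runs [select_model()] on the requested specimen
#' under the configuration, and returns (optionally writing as JSON) a
#' self-contained report: configuration, input file hash, Davies gate,
#' candidate AICs and the chosen fit. Reports are byte-identical under an
#' identical configuration and seed. When `plot_file` is given, a plot of
#' centrum length against vertebra number with the fitted mean function,
#' break points with +/- 1 SE bars, and the transition point marker is
#' written as PNG.
#'
#' @param series_file Path to the canonical series CSV.
#' @param specimen_id Specimen to fit.
#' @param config A [run_config()].
#' @param out Optional path for the JSON report.
#' @param plot_file Optional path for a PNG plot.
#' @return The report, an invisible list.
#' @export
cmd_fit <- function(series_file, specimen_id, config = run_config(),
                    out = NULL, plot_file = NULL) {
  series <- read_series_table(series_file)
  if (!specimen_id %in% names(series)) {
    stop_caudseg(sprintf("unknown specimen id '%s'; available: %s", specimen_id,
                         paste(names(series), collapse = ", ")),
                 "caudseg_validation_error")
  }
  s <- series[[specimen_id]]
  res <- select_model(s, max_breaks = config$max_breaks, alpha = config$alpha,
                      allow_discontinuous = config$allow_discontinuous,
                      seed = config$seed, n_boot = config$n_boot,
                      max_iter = config$max_iter, davies_k = config$davies_k)
  report <- list(
    config = unclass(config),
    inputs = .provenance(list(series_file = series_file)),
    selection = .selection_report(res)
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 800, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_selection(res, s)
  }
  invisible(report)
}

#' Plot a fitted caudal series
#'
#' @param result A `model_selection_result`.
#' @param series The [caudal_series] it was fitted to.
#' @param ... Passed to `plot()`.
#' @export
plot_selection <- function(result, series, ...) {
  x <- series$positions; y <- series$lengths
  graphics::plot(x, y, pch = 16, xlab = "vertebra number",
                 ylab = "centrum length (mm)",
                 main = sprintf("%s (%s)", series$specimen_id, result$chosen), ...)
  fit <- result$chosen_fit
  if (inherits(fit, "segmented_fit")) {
    xx <- seq(min(x), max(x), length.out = 200)
    graphics::lines(xx, predict.segmented_fit(fit, xx), col = "red3", lwd = 2)
    y0 <- min(y) - 0.04 * diff(range(y))
    graphics::points(fit$breakpoints, rep(y0, fit$n_breaks), pch = 17, col = "red3")
    graphics::segments(fit$breakpoints - fit$breakpoint_se, y0,
                       fit$breakpoints + fit$breakpoint_se, y0, col = "red3")
  } else if (inherits(fit, "discontinuous_fit")) {
    lo <- x < fit$split_position
    graphics::lines(x[lo], fit$intercepts[1] + fit$slopes[1] * x[lo],
                    col = "red3", lwd = 2)
    graphics::lines(x[!lo], fit$intercepts[2] + fit$slopes[2] * x[!lo],
                    col = "red3", lwd = 2)
  } else {
    graphics::abline(fit$intercept, fit$slope, col = "red3", lwd = 2)
  }
  if (!is.na(series$transition_point)) {
    graphics::arrows(series$transition_point, max(y), series$transition_point,
                     max(y) - 0.12 * diff(range(y)), length = 0.1, col = "blue3")
  }
  invisible(NULL)
}

#' Run the full study pipeline and consolidate a report
#'
#' Batch model selection over every series, the break/transition proximity
#' randomization test over the eligible specimens, and the femur-scaled
#' allometric regressions (all samples plus every locomotor subset with
#' enough data), consolidated into one report. Per-specimen failures are
#' isolated and counted as warnings; an empty proximity section (no eligible
#' specimen) is reported, not fatal.
#'
#' @param series_file Path to the canonical series CSV.
#' @param specimens_file Path to the specimens CSV.
#' @param config A [run_config()].
#' @param out Optional path for the JSON report.
#' @return The report, an invisible list with sections `model_selection`,
#'   `proximity`, `allometry`, plus `config`, `inputs` and `n_warnings`.
#' @export
cmd_pipeline <- function(series_file, specimens_file, config = run_config(),
                         out = NULL) {
  series <- read_series_table(series_file)
  specimens <- read_specimen_table(specimens_file)
  n_warn <- 0L

  results <- screen_batch(series, max_breaks = config$max_breaks,
                          alpha = config$alpha,
                          allow_discontinuous = config$allow_discontinuous,
                          seed = config$seed, n_boot = config$n_boot,
                          max_iter = config$max_iter, davies_k = config$davies_k)
  failed <- vapply(results, inherits, logical(1), "model_selection_failure")
  n_warn <- n_warn + sum(failed)

  prox <- tryCatch(
    proximity_test(results[!failed], reps = config$reps, seed = config$seed),
    caudseg_error = function(e) NULL
  )
  if (is.null(prox)) n_warn <- n_warn + 1L

  samples <- build_samples(specimens)
  allo <- list()
  for (sub in .allometry_subsets) {
    fit <- tryCatch(allometry_regress(samples, sub), caudseg_error = function(e) NULL)
    if (!is.null(fit)) {
      allo[[sub]] <- list(f_statistic = fit$f_statistic, df = fit$df,
                          p_value = fit$p_value, slope = fit$slope,
                          intercept = fit$intercept, n = fit$n)
    }
  }

  report <- list(
    config = unclass(config),
    inputs = .provenance(list(series_file = series_file,
                              specimens_file = specimens_file)),
    model_selection = lapply(results, function(r) {
      if (inherits(r, "model_selection_failure")) {
        list(specimen_id = r$specimen_id, failed = TRUE, message = r$message)
      } else .selection_report(r)
    }),
    proximity = if (is.null(prox)) list(empty = TRUE) else list(
      n_closer = prox$n_closer, n_total = prox$n_total,
      binomial_p = prox$binomial_p,
      per_specimen = prox$per_specimen, excluded = prox$excluded
    ),
    allometry = allo,
    n_warnings = n_warn
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null",
                         dataframe = "rows")
  }
  invisible(report)
}

#' Export the per-specimen proximity quantities as CSV
#'
#' Writes the actual and randomized-null nearest-break distances per
#' specimen, the quantities behind the proximity scatter.
#'
#' @param prox A `proximity_test_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_proximity_csv <- function(prox, path) {
  stopifnot(inherits(prox, "proximity_test_result"))
  write.csv(prox$per_specimen, path, row.names = FALSE)
  invisible(path)
}
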