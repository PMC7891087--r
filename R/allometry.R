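## Femur-scaled allometry: tail length and snout-sacrum length are each
## divided by the femur length of the individual they were measured from
## (femur length as the body-size proxy), and the snout-sacrum ratio is
## regressed on the tail ratio, overall and within locomotor subgroups.

#' Build femur-scaled allometric samples from specimen records
#'
#' Computes, per specimen, `tail_femur_ratio = tail_mm / femur_mm` and
#' `snout_sacrum_femur_ratio = snout_sacrum_mm / femur_mm`. Specimens without
#' a femur are skipped with a warning. When `pair_within_taxon = TRUE`,
#' specimens of the same taxon holding only one of the two measurements are
#' paired into a single sample (each measurement scaled by its own
#' specimen's femur), flagged `same_individual = FALSE`; this mirrors
#' datasets where the tail and the presacral column come from different
#' individuals. Samples lacking the snout-sacrum ratio are kept (they still
#' inform the observed ratio range) but are excluded from regression by
#' [allometry_regress()].
#'
#' @param records A `specimen_table` (see [read_specimen_table()]) or
#'   equivalent data frame.
#' @param pair_within_taxon Pair complementary single-measurement specimens
#'   of the same taxon (default `FALSE`).
#' @return A data frame with class `allometry_samples`: `specimen_id`,
#'   `taxon`, `tail_femur_ratio`, `snout_sacrum_femur_ratio`,
#'   `same_individual`, `locomotor_class`, `largest_of_species`.
#' @export
build_samples <- function(records, pair_within_taxon = FALSE) {
  stopifnot(is.data.frame(records))
  no_femur <- is.na(records$femur_mm)
  if (any(no_femur)) {
    warning(sprintf("skipping %d specimen(s) without femur length: %s",
                    sum(no_femur),
                    paste(records$specimen_id[no_femur], collapse = ", ")))
    records <- records[!no_femur, , drop = FALSE]
  }
  samples <- data.frame(
    specimen_id = records$specimen_id,
    taxon = records$taxon,
    tail_femur_ratio = records$tail_mm / records$femur_mm,
    snout_sacrum_femur_ratio = records$snout_sacrum_mm / records$femur_mm,
    same_individual = !is.na(records$tail_mm) & !is.na(records$snout_sacrum_mm),
    locomotor_class = records$locomotor_class,
    largest_of_species = records$largest_of_species,
    femur_mm = records$femur_mm,
    stringsAsFactors = FALSE
  )
  if (pair_within_taxon) {
    tail_only <- which(!is.na(samples$tail_femur_ratio) &
                         is.na(samples$snout_sacrum_femur_ratio))
    ss_only <- which(is.na(samples$tail_femur_ratio) &
                       !is.na(samples$snout_sacrum_femur_ratio))
    for (i in tail_only) {
      j <- ss_only[match(samples$taxon[i], samples$taxon[ss_only])]
      if (is.na(j)) next
      samples$snout_sacrum_femur_ratio[i] <- samples$snout_sacrum_femur_ratio[j]
      samples$same_individual[i] <- FALSE
      ss_only <- setdiff(ss_only, j)
    }
  }
  out_of_band <- which(!is.na(samples$tail_femur_ratio) &
                         (samples$tail_femur_ratio <= 0.5 |
                            samples$tail_femur_ratio >= 20))
  if (length(out_of_band)) {
    warning(sprintf("tail:femur ratio outside the sanity band (0.5, 20) for: %s",
                    paste(samples$specimen_id[out_of_band], collapse = ", ")))
  }
  class(samples) <- c("allometry_samples", "data.frame")
  samples
}

.allometry_subsets <- c("all", "largest_only", "bipeds", "quadrupeds",
                        "bipeds_facultative", "quadrupeds_facultative")

.subset_samples <- function(samples, subset) {
  switch(subset,
    all = samples,
    largest_only = {
      keep <- unlist(lapply(split(seq_len(nrow(samples)), samples$taxon),
                            function(idx) idx[which.max(samples$femur_mm[idx])]))
      samples[sort(keep), , drop = FALSE]
    },
    bipeds = samples[samples$locomotor_class %in% "biped", , drop = FALSE],
    quadrupeds = samples[samples$locomotor_class %in% "quadruped", , drop = FALSE],
    bipeds_facultative =
      samples[samples$locomotor_class %in% c("biped", "facultative_biped"), , drop = FALSE],
    quadrupeds_facultative =
      samples[samples$locomotor_class %in% c("quadruped", "facultative_biped"), , drop = FALSE]
  )
}

#' Regress the snout-sacrum ratio on the tail ratio
#'
#' Ordinary least-squares regression of `snout_sacrum_femur_ratio` on
#' `tail_femur_ratio` over a chosen subset of the samples. The F statistic is
#' the squared t statistic of the slope, on (1, n - 2) degrees of freedom.
#' Subsets follow the locomotor divisions: obligate bipeds, obligate
#' quadrupeds, each optionally pooled with facultative bipeds, and a
#' largest-individual-per-taxon restriction that counters over-representation
#' of multi-specimen species.
#'
#' @param samples An `allometry_samples` data frame (see [build_samples()]).
#' @param subset One of `"all"`, `"largest_only"`, `"bipeds"`,
#'   `"quadrupeds"`, `"bipeds_facultative"`, `"quadrupeds_facultative"`.
#' @return An object of class `allometry_fit`: `slope`, `intercept`,
#'   `f_statistic`, `df = c(1, n - 2)`, `p_value`, `residual_variance`, `n`,
#'   `subset`, plus `x_mean`, `x_ssq` and `x_range` used for intervals.
#' @export
allometry_regress <- function(samples, subset = "all") {
  subset <- match.arg(subset, .allometry_subsets)
  sub <- .subset_samples(samples, subset)
  sub <- sub[!is.na(sub$tail_femur_ratio) & !is.na(sub$snout_sacrum_femur_ratio), ,
             drop = FALSE]
  n <- nrow(sub)
  if (n < 4) {
    stop_caudseg(sprintf("subset '%s' has only %d usable sample(s); need >= 4",
                         subset, n), "caudseg_validation_error")
  }
  xr <- sub$tail_femur_ratio; yr <- sub$snout_sacrum_femur_ratio
  fit <- lm(yr ~ xr)
  sm <- summary(fit)
  tval <- sm$coefficients["xr", "t value"]
  fstat <- tval^2
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    f_statistic = fstat,
    df = c(1L, n - 2L),
    p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
    residual_variance = sm$sigma^2,
    n = n,
    subset = subset,
    x_mean = mean(xr),
    x_ssq = sum((xr - mean(xr))^2),
    x_range = range(xr)
  ), class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("<allometry_fit> [%s] ss:femur = %.4g %+.4g * tail:femur  (n = %d)\n",
              x$subset, x$intercept, x$slope, x$n))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  invisible(x)
}

#' Interval estimate of snout-sacrum length from a tail:femur ratio
#'
#' Converts the regression of [allometry_regress()] into an interval for the
#' snout-sacrum length (mm) of a specimen with a given tail:femur ratio and
#' femur length: an interval on the ratio scale is computed at
#' `tail_femur_ratio` and multiplied by `femur_mm`. `type = "prediction"`
#' (the default) gives the specimen-level prediction interval
#' `t * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)`; `type = "confidence"` the
#' narrower mean-response interval (no leading 1). Requests more than 50%
#' beyond the observed ratio range are flagged as extrapolation.
#'
#' @param fit An `allometry_fit`.
#' @param tail_femur_ratio Tail:femur ratio of the target specimen.
#' @param femur_mm Femur length of the target specimen (mm).
#' @param level Coverage level (default 0.95).
#' @param type `"prediction"` or `"confidence"`.
#' @return Named numeric vector `c(lower, upper)` in mm, with attributes
#'   `point` (point estimate, mm) and `extrapolated` (logical flag).
#' @export
predict_interval <- function(fit, tail_femur_ratio, femur_mm, level = 0.95,
                             type = c("prediction", "confidence")) {
  stopifnot(inherits(fit, "allometry_fit"))
  type <- match.arg(type)
  if (tail_femur_ratio <= 0 || femur_mm <= 0) {
    stop_caudseg("ratio and femur length must be positive", "caudseg_validation_error")
  }
  x0 <- tail_femur_ratio
  mu <- fit$intercept + fit$slope * x0
  lev2 <- (1 / fit$n) + (x0 - fit$x_mean)^2 / fit$x_ssq
  se <- sqrt(fit$residual_variance * (if (type == "prediction") 1 + lev2 else lev2))
  tq <- qt(1 - (1 - level) / 2, fit$df[2])
  lower <- (mu - tq * se) * femur_mm
  upper <- (mu + tq * se) * femur_mm
  width <- diff(fit$x_range)
  extrapolated <- x0 < fit$x_range[1] - 0.5 * width ||
    x0 > fit$x_range[2] + 0.5 * width
  if (extrapolated) {
    warning(sprintf("tail:femur ratio %.3g lies > 50%% outside the observed range [%.3g, %.3g]",
                    x0, fit$x_range[1], fit$x_range[2]))
  }
  structure(c(lower = lower, upper = upper),
            point = mu * femur_mm, extrapolated = extrapolated)
}
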