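## Synthetic caudal series and allometric cohorts. The generator emulates the
## structure the pipeline assumes: a continuous piecewise-linear mean profile
## of centrum length along the tail (typically short proximal centra, a
## region of longer centra, then a long taper), i.i.d. Gaussian measurement
## noise, optional missing vertebrae, a transition point tied to one of the
## breaks, and specimen-level femur/tail/snout-sacrum measurements in which
## the femur-scaled ratios have a controlled correlation.

#' Specify a synthetic caudal series
#'
#' @param n_vertebrae Number of vertebrae.
#' @param break_positions Ordered break positions, strictly inside
#'   `(1, n_vertebrae)`.
#' @param segment_slopes One slope (mm per vertebra) per segment; length must
#'   be `length(break_positions) + 1`.
#' @param start_length Mean centrum length at vertebra 1 (mm, default 40).
#' @param noise_sd Gaussian measurement noise SD (mm).
#' @param missing_positions Integer positions to drop (missing vertebrae).
#' @param transition_break Index of the break the transition point is tied to
#'   (default 2, or the last break when fewer exist; `NA` for no transition
#'   point).
#' @param transition_offset Signed vertebra offset of the transition point
#'   from that break (default 0).
#' @param seed Optional integer seed.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(n_vertebrae, break_positions, segment_slopes,
                        start_length = 40, noise_sd = 0,
                        missing_positions = integer(), transition_break = 2,
                        transition_offset = 0, seed = NULL) {
  n_vertebrae <- as.integer(n_vertebrae)
  break_positions <- as.numeric(break_positions)
  if (length(segment_slopes) != length(break_positions) + 1) {
    stop_caudseg("need one segment slope per segment (breaks + 1)",
                 "caudseg_validation_error")
  }
  if (length(break_positions) &&
      (is.unsorted(break_positions, strictly = TRUE) ||
         any(break_positions <= 1) || any(break_positions >= n_vertebrae))) {
    stop_caudseg("break positions must be strictly increasing and inside (1, n_vertebrae)",
                 "caudseg_validation_error")
  }
  if (noise_sd < 0 || start_length <= 0) {
    stop_caudseg("noise_sd must be >= 0 and start_length > 0",
                 "caudseg_validation_error")
  }
  if (length(break_positions) == 0) transition_break <- NA_integer_
  if (!is.na(transition_break)) {
    transition_break <- min(as.integer(transition_break), length(break_positions))
  }
  structure(list(
    n_vertebrae = n_vertebrae,
    break_positions = break_positions,
    segment_slopes = as.numeric(segment_slopes),
    start_length = start_length,
    noise_sd = noise_sd,
    missing_positions = as.integer(missing_positions),
    transition_break = transition_break,
    transition_offset = transition_offset,
    seed = seed
  ), class = "series_spec")
}

#' Piecewise-linear mean centrum length of a series spec
#'
#' @param spec A [series_spec].
#' @param positions Vertebra numbers at which to evaluate (default all).
#' @return Mean centrum lengths (mm).
#' @export
series_mean_profile <- function(spec, positions = seq_len(spec$n_vertebrae)) {
  sl <- spec$segment_slopes
  mu <- spec$start_length + sl[1] * (positions - 1)
  for (j in seq_along(spec$break_positions)) {
    mu <- mu + (sl[j + 1] - sl[j]) * pmax(positions - spec$break_positions[j], 0)
  }
  mu
}

#' The default dinosaur-like series specification
#'
#' A three-segment profile emulating the commonly observed caudal pattern: a
#' short proximal series of decreasing centrum lengths, a series of longer
#' centra (containing the longest in the tail), and a long tapering distal
#' series. Breaks sit at 20% and 40% of the series; slopes are
#' -2.0 / +1.5 / -0.9 mm per vertebra at the reference length of 60
#' vertebrae, rescaled by `60 / n_vertebrae` for other lengths so the profile
#' shape (and positivity) is preserved; the transition point sits at the
#' second break. Noise defaults to 5% of the mean centrum length.
#'
#' @param n_vertebrae Series length (default 60).
#' @param noise_frac Noise SD as a fraction of the mean profile value
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @param ... Overrides passed to [series_spec()].
#' @return A [series_spec].
#' @export
dinosaur_series_spec <- function(n_vertebrae = 60, noise_frac = 0.05,
                                 seed = NULL, ...) {
  breaks <- round(c(0.2, 0.4) * n_vertebrae)
  slopes <- c(-2.0, 1.5, -0.9) * 60 / n_vertebrae
  spec0 <- series_spec(n_vertebrae, breaks, slopes, start_length = 40,
                       noise_sd = 0, seed = seed)
  noise_sd <- noise_frac * mean(series_mean_profile(spec0))
  args <- list(n_vertebrae = n_vertebrae, break_positions = breaks,
               segment_slopes = slopes, start_length = 40,
               noise_sd = noise_sd, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(series_spec, args)
}

#' A three-break series specification
#'
#' Variant of the dinosaurian profile with an extra regime: decrease,
#' increase, near-plateau, then taper (slopes -2.0 / +1.5 / -0.2 / -1.2 mm
#' per vertebra at the 60-vertebra reference, rescaled as in
#' [dinosaur_series_spec()]), breaks at 20%, 40% and 67% of the series.
#'
#' @inheritParams dinosaur_series_spec
#' @return A [series_spec].
#' @export
three_break_series_spec <- function(n_vertebrae = 60, noise_frac = 0.05,
                                    seed = NULL, ...) {
  breaks <- round(c(0.2, 0.4, 0.67) * n_vertebrae)
  slopes <- c(-2.0, 1.5, -0.2, -1.2) * 60 / n_vertebrae
  spec0 <- series_spec(n_vertebrae, breaks, slopes, start_length = 40,
                       noise_sd = 0, seed = seed)
  noise_sd <- noise_frac * mean(series_mean_profile(spec0))
  args <- list(n_vertebrae = n_vertebrae, break_positions = breaks,
               segment_slopes = slopes, start_length = 40,
               noise_sd = noise_sd, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(series_spec, args)
}

#' Generate a synthetic caudal series
#'
#' Draws centrum lengths as the continuous piecewise-linear mean profile of
#' the spec plus i.i.d. Gaussian noise, removes any `missing_positions`, and
#' places the transition point at the designated break plus
#' `transition_offset` (rounded to a vertebra). Deterministic under the
#' spec's seed. A spec whose mean profile is non-positive anywhere is
#' rejected.
#'
#' @param spec A [series_spec].
#' @param specimen_id,taxon Identifiers for the resulting series.
#' @return A [caudal_series] with attributes `true_breaks` (the spec's break
#'   positions) and `tail_mm` (sum of all generated centrum lengths, before
#'   any removal of missing positions).
#' @export
generate_series <- function(spec, specimen_id = "synthetic", taxon = "Synthetica") {
  stopifnot(inherits(spec, "series_spec"))
  positions <- seq_len(spec$n_vertebrae)
  mu <- series_mean_profile(spec, positions)
  if (any(mu <= 0)) {
    stop_caudseg(sprintf("spec rejected: mean centrum length non-positive at vertebra %d",
                         positions[which(mu <= 0)[1]]),
                 "caudseg_validation_error")
  }
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  # centrum lengths are physically positive; the rare noise draw that crosses
  # zero (possible when the profile tapers to a few noise SDs) is redrawn
  lengths <- mu + rnorm(spec$n_vertebrae, 0, spec$noise_sd)
  for (attempt in seq_len(50)) {
    if (all(lengths > 0)) break
    lengths <- mu + rnorm(spec$n_vertebrae, 0, spec$noise_sd)
  }
  if (any(lengths <= 0)) {
    stop_caudseg("could not generate positive centrum lengths; reduce noise_sd relative to the profile minimum",
                 "caudseg_validation_error")
  }
  tail_mm <- sum(lengths)
  keep <- !(positions %in% spec$missing_positions)
  tp <- NA_real_
  if (!is.na(spec$transition_break) && length(spec$break_positions)) {
    tp <- round(spec$break_positions[spec$transition_break] + spec$transition_offset)
    tp <- min(max(tp, 1), spec$n_vertebrae)
  }
  out <- caudal_series(specimen_id, taxon,
                       positions = positions[keep], lengths = lengths[keep],
                       transition_point = tp, complete = TRUE)
  attr(out, "true_breaks") <- spec$break_positions
  attr(out, "tail_mm") <- tail_mm
  out
}

#' Specify a synthetic cohort
#'
#' @param n_specimens Number of specimens (default 25, the size of a typical
#'   break-point cohort).
#' @param n_vertebrae_range Integer range of series lengths (default
#'   `c(20, 90)`).
#' @param noise_frac Noise SD as a fraction of mean centrum length
#'   (default 0.05).
#' @param ratio_range Range of tail:femur ratios (default `c(1.2, 12.4)`,
#'   the span observed across dinosaurs).
#' @param femur_range Range of femur lengths in mm (default `c(80, 1200)`).
#' @param correlation Target correlation between tail:femur and
#'   snout-sacrum:femur ratios (default 0, emulating their independence).
#' @param n_breaks Number of true breaks per series: 2 (default,
#'   [dinosaur_series_spec()]) or 3 ([three_break_series_spec()]).
#' @param transition_offset Offset of the transition point from its break.
#' @param seed Optional integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 25, n_vertebrae_range = c(20, 90),
                        noise_frac = 0.05, ratio_range = c(1.2, 12.4),
                        femur_range = c(80, 1200), correlation = 0,
                        n_breaks = 2, transition_offset = 0, seed = NULL) {
  if (abs(correlation) > 1) {
    stop_caudseg("infeasible correlation (|r| > 1)", "caudseg_validation_error")
  }
  for (rg in list(n_vertebrae_range, ratio_range, femur_range)) {
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2]) {
      stop_caudseg("ranges must be positive and ordered", "caudseg_validation_error")
    }
  }
  stopifnot(n_specimens >= 1, n_breaks %in% c(2, 3))
  structure(list(
    n_specimens = as.integer(n_specimens),
    n_vertebrae_range = as.integer(n_vertebrae_range),
    noise_frac = noise_frac,
    ratio_range = ratio_range,
    femur_range = femur_range,
    correlation = correlation,
    n_breaks = as.integer(n_breaks),
    transition_offset = transition_offset,
    seed = seed
  ), class = "cohort_spec")
}

#' Generate a synthetic cohort of series and specimen records
#'
#' For each specimen, draws a series length and a tail:femur ratio and femur
#' length, generates a caudal series from the preset profile, and rescales
#' its centrum lengths so that the tail length (the sum of all generated
#' centrum lengths) equals `ratio * femur` exactly. Snout-sacrum lengths are
#' drawn so that the cohort's snout-sacrum:femur ratios have the target
#' correlation with the tail:femur ratios (around a mean ratio of 2.5, SD
#' 0.6). Locomotor classes are assigned at random (biped / quadruped /
#' facultative biped at 0.5 / 0.3 / 0.2).
#'
#' @param spec A [cohort_spec].
#' @return A list with components `series` (list of [caudal_series]) and
#'   `specimens` (a `specimen_table` data frame).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  n <- spec$n_specimens
  nv <- if (spec$n_vertebrae_range[1] == spec$n_vertebrae_range[2])
    rep(spec$n_vertebrae_range[1], n) else
      sample(seq(spec$n_vertebrae_range[1], spec$n_vertebrae_range[2]), n,
             replace = TRUE)
  ratio <- runif(n, spec$ratio_range[1], spec$ratio_range[2])
  femur <- runif(n, spec$femur_range[1], spec$femur_range[2])
  series_seeds <- sample.int(2^31 - 2, n)
  maker <- if (spec$n_breaks == 2) dinosaur_series_spec else three_break_series_spec

  series <- vector("list", n)
  tail_mm <- numeric(n)
  for (i in seq_len(n)) {
    id <- sprintf("SYN%03d", i)
    sp <- maker(n_vertebrae = nv[i], noise_frac = spec$noise_frac,
                seed = series_seeds[i], transition_offset = spec$transition_offset)
    s <- generate_series(sp, specimen_id = id, taxon = sprintf("Synthetica_%03d", i))
    target_tail <- ratio[i] * femur[i]
    scale <- target_tail / attr(s, "tail_mm")
    s$lengths <- s$lengths * scale
    attr(s, "tail_mm") <- target_tail
    series[[i]] <- s
    tail_mm[i] <- target_tail
  }

  r <- spec$correlation
  t_std <- if (n >= 2 && sd(ratio) > 0) (ratio - mean(ratio)) / sd(ratio) else rep(0, n)
  z <- rnorm(n)
  ss_ratio <- 2.5 + 0.6 * (r * t_std + sqrt(1 - r^2) * z)
  ss_ratio <- pmax(ss_ratio, 0.2)
  specimens <- data.frame(
    specimen_id = vapply(series, function(s) s$specimen_id, character(1)),
    taxon = vapply(series, function(s) s$taxon, character(1)),
    femur_mm = femur,
    snout_sacrum_mm = ss_ratio * femur,
    tail_mm = tail_mm,
    locomotor_class = sample(.locomotor_classes, n, replace = TRUE,
                             prob = c(0.5, 0.3, 0.2)),
    largest_of_species = TRUE,
    stringsAsFactors = FALSE
  )
  class(specimens) <- c("specimen_table", "data.frame")
  list(series = series, specimens = specimens)
}
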