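## Regression fits for centrum length on vertebra number: ordinary linear,
## segmented (continuous piecewise-linear with estimated break points, fitted
## by iterative linearization with bootstrap restarting), and a discontinuous
## two-regime model.

#' Gaussian maximum-likelihood AIC from a residual sum of squares
#'
#' `AIC = n * log(2 * pi * RSS / n) + n + 2 * (n_coef + 1)`, i.e. the Gaussian
#' log-likelihood with the error variance at its maximum-likelihood value
#' `RSS / n`, and the variance counted as an estimated parameter. This is the
#' same convention as `stats::AIC()` on an `lm` fit. For segmented fits the
#' estimated break points count toward `n_coef`.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of observations.
#' @param n_coef Number of mean-function coefficients (excluding the variance).
#' @return The AIC value (`-Inf` for an exact fit with `rss = 0`).
#' @export
aic_gaussian <- function(rss, n, n_coef) {
  if (rss < 0) stop_caudseg("rss must be non-negative", "caudseg_validation_error")
  if (rss == 0) return(-Inf)
  n * log(2 * pi * rss / n) + n + 2 * (n_coef + 1)
}

#' Ordinary linear regression of centrum length on vertebra number
#'
#' @param x Numeric vector of vertebra numbers.
#' @param y Numeric vector of centrum lengths (mm), parallel to `x`.
#' @return An object of class `linear_fit` with components `intercept`,
#'   `slope`, `rss`, `n`, `n_coef`, `log_likelihood`, `aic`, `fitted`.
#' @examples
#' f <- fit_linear(1:10, 2 * (1:10) + 1)
#' f$slope   # 2
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop_caudseg("fit_linear needs >= 3 paired observations",
                 "caudseg_validation_error")
  }
  if (length(unique(x)) < 2) {
    stop_caudseg("degenerate x (all values equal)", "caudseg_singular_error")
  }
  fit <- lm.fit(cbind(`(Intercept)` = 1, x = x), y)
  rss <- sum(fit$residuals^2)
  ll <- if (rss > 0) -n / 2 * (log(2 * pi * rss / n) + 1) else Inf
  structure(list(
    intercept = unname(fit$coefficients[1]),
    slope = unname(fit$coefficients[2]),
    rss = rss, n = n, n_coef = 2L,
    log_likelihood = ll,
    aic = aic_gaussian(rss, n, 2L),
    fitted = unname(fit$fitted.values)
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4g %+.4g x  (n = %d, RSS = %.4g, AIC = %.4g)\n",
              x$intercept, x$slope, x$n, x$rss, x$aic))
  invisible(x)
}

# hinge basis pmax(x - psi_j, 0), one column per break
.hinge <- function(x, psi) {
  out <- outer(x, psi, "-")
  out[out < 0] <- 0
  out
}

.min_psi_gap <- function(x) max(diff(range(x)) * 1e-6, 1e-9)

# One pass of the iterative linearization at fixed starting psi.
# Regress y on [1, x, U_j = (x - psi_j)_+, V_j = -1{x > psi_j}]; the slope
# change delta_j is the coefficient on U_j and the gap gamma_j on V_j; the
# update psi_j <- psi_j + gamma_j / delta_j drives the gap to zero. The RSS
# surface has kinks at the data positions, so the raw update can overshoot
# and oscillate around an optimum; a worsening step is halved (up to 5
# times), and the best iterate by constrained RSS is the one reported.
.seg_iterate <- function(x, y, psi, max_iter, tol) {
  n <- length(x)
  rng <- range(x)
  k <- length(psi)
  clamped <- FALSE
  converged <- FALSE
  iter <- 0L
  # preallocated designs: constrained (intercept, x, hinges) and working
  # (plus gap indicators); only the psi-dependent columns are refilled
  Xc <- cbind(1, x, matrix(0, n, k))
  X <- cbind(1, x, matrix(0, n, 2 * k))
  const_rss <- function(p) {
    Xc[, 3:(2 + k)] <- .hinge(x, p)
    sum(.lm.fit(Xc, y)$residuals^2)
  }
  best_psi <- psi
  best_rss <- rss_cur <- const_rss(psi)
  for (iter in seq_len(max_iter)) {
    X[, 3:(2 + k)] <- .hinge(x, psi)
    X[, (3 + k):(2 + 2 * k)] <- -(outer(x, psi, ">"))
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X)) {
      stop_caudseg("segmented design is rank-deficient at current break points",
                   "caudseg_unfittable_error")
    }
    cf <- fit$coefficients
    delta <- cf[3:(2 + k)]
    gamma <- cf[(3 + k):(2 + 2 * k)]
    if (any(abs(delta) < 1e-10)) {
      stop_caudseg("slope change numerically zero; candidate discarded",
                   "caudseg_unfittable_error")
    }
    step <- gamma / delta
    h <- 1
    rss_new <- NA_real_
    repeat {
      psi_new <- psi + h * step
      if (any(psi_new <= rng[1]) || any(psi_new >= rng[2])) {
        if (clamped) { h <- 0; break }
        eps <- diff(rng) * 1e-3
        psi_new <- pmin(pmax(psi_new, rng[1] + eps), rng[2] - eps)
        clamped <- TRUE
      }
      psi_new <- sort(psi_new)
      if (k > 1 && any(diff(psi_new) < .min_psi_gap(x))) {
        stop_caudseg("break points collapsed; candidate discarded",
                     "caudseg_unfittable_error")
      }
      rss_new <- const_rss(psi_new)
      if (h <= 1 / 32 || rss_new <= rss_cur + 1e-12) break
      h <- h / 2
    }
    if (h == 0) { converged <- FALSE; break }
    psi <- psi_new
    rss_cur <- rss_new
    if (rss_cur < best_rss) { best_rss <- rss_cur; best_psi <- psi }
    if (max(abs(h * step)) < tol) { converged <- TRUE; break }
  }
  list(psi = unname(best_psi), rss = best_rss, converged = converged, iter = iter)
}

# coordinate-wise local refinement of psi by direct RSS minimisation within
# +/- 1 vertebra per break: the linearized update can stall just off an
# optimum that sits at a kink of the piecewise-smooth RSS surface
.seg_polish <- function(x, y, psi) {
  const_rss <- function(p) sum(.lm.fit(cbind(1, x, .hinge(x, p)), y)$residuals^2)
  rng <- range(x)
  eps <- diff(rng) * 1e-3
  gap <- .min_psi_gap(x)
  k <- length(psi)
  rss_cur <- const_rss(psi)
  for (j in seq_len(k)) {
    lower <- max(rng[1] + eps, if (j > 1) psi[j - 1] + gap else -Inf, psi[j] - 1)
    upper <- min(rng[2] - eps, if (j < k) psi[j + 1] - gap else Inf, psi[j] + 1)
    if (lower >= upper) next
    opt <- optimize(function(p) { p2 <- psi; p2[j] <- p; const_rss(p2) },
                    c(lower, upper), tol = 1e-7)
    if (opt$objective < rss_cur) { psi[j] <- opt$minimum; rss_cur <- opt$objective }
  }
  psi
}

# constrained fit and break-point standard errors at fixed psi
.seg_finalize <- function(x, y, psi, converged, iter) {
  n <- length(x)
  k <- length(psi)
  # unconstrained pass at the accepted psi, for SE(psi) = SE(gamma)/|delta|
  U <- .hinge(x, psi)
  V <- -1 * (outer(x, psi, ">"))
  X <- cbind(1, x, U, V)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_caudseg("segmented design is rank-deficient at final break points",
                 "caudseg_unfittable_error")
  }
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  delta <- cf[3:(2 + k)]
  if (any(abs(delta) < 1e-10)) {
    stop_caudseg("slope change numerically zero; candidate discarded",
                 "caudseg_unfittable_error")
  }
  dfree <- n - ncol(X)
  sigma2 <- if (dfree > 0) sum(res^2) / dfree else NA_real_
  covm <- tryCatch(chol2inv(qr.R(qx)) * sigma2, error = function(e) NULL)
  se_gamma <- if (is.null(covm)) rep(NA_real_, k) else
    sqrt(diag(covm))[(3 + k):(2 + 2 * k)]
  # constrained fit (gamma = 0) at final psi: the reported mean function
  Xc <- cbind(1, x, U)
  cfit <- lm.fit(Xc, y)
  rss <- sum(cfit$residuals^2)
  list(
    psi = unname(psi),
    se_psi = unname(se_gamma / abs(delta)),
    coef = unname(cfit$coefficients),
    fitted = unname(cfit$fitted.values),
    rss = rss,
    converged = converged,
    iter = iter
  )
}

#' Segmented (broken-stick) regression with estimated break points
#'
#' Fits a continuous piecewise-linear regression of `y` on `x` with
#' `n_breaks` break points by iterative linearization: at the current break
#' estimates psi, `y` is regressed on the intercept, `x`, the hinge terms
#' `(x - psi_j)_+` and the gap indicators `-1{x > psi_j}`; the ratio of the
#' gap coefficient to the slope-change coefficient updates each psi, and
#' iteration stops when the largest update falls below `tol` (in vertebra
#' units) or after `max_iter` iterations. Starting values default to the
#' `j/(n_breaks+1)` quantiles of the interior `x` values.
#'
#' Because the RSS surface is non-convex, the fit is restarted by bootstrap:
#' `n_boot` case-resampled refits are run, each solution is re-evaluated by
#' re-iterating on the original data, and the break points with the smallest
#' original-data RSS are kept. Reported coefficients come from the
#' constrained fit (zero gap) at the final break points; break-point standard
#' errors are `SE(gamma_j) / |delta_j|` from the final unconstrained pass.
#'
#' @param x,y Numeric vectors: vertebra numbers and centrum lengths (mm).
#' @param n_breaks Integer number of break points, 1 to 4.
#' @param starts Optional numeric vector of starting break positions.
#' @param n_boot Number of bootstrap restarts (default 50).
#' @param max_iter Maximum iterations per start (default 10).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param tol Convergence tolerance on the break-point update, vertebra units.
#' @param extra_starts Optional list of additional starting vectors to try.
#' @return An object of class `segmented_fit`: `n_breaks`, `breakpoints`,
#'   `breakpoint_se`, `intercept`, `base_slope`, `slope_changes`, `rss`,
#'   `aic` (break points counted as parameters: `n_coef = 2 + 2 * n_breaks`),
#'   `converged`, `n_iterations`, `fitted`, plus the data `x`, `y`.
#' @examples
#' x <- 1:30
#' y <- ifelse(x <= 10, 30 - 1 * x, 20 + 1 * (x - 10))
#' fit_segmented(x, y, n_breaks = 1, seed = 1)$breakpoints  # 10
#' @export
fit_segmented <- function(x, y, n_breaks, starts = NULL, n_boot = 50,
                          max_iter = 10, seed = NULL, tol = 1e-4,
                          extra_starts = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  n_breaks <- as.integer(n_breaks)
  if (n_breaks < 1L || n_breaks > 4L) {
    stop_caudseg("n_breaks must be between 1 and 4", "caudseg_validation_error")
  }
  if (length(y) != n || n < 2 * (n_breaks + 1) + 1) {
    stop_caudseg(sprintf("need at least %d observations for %d break(s)",
                         2 * (n_breaks + 1) + 1, n_breaks),
                 "caudseg_validation_error")
  }
  if (length(unique(x)) < n_breaks + 2) {
    stop_caudseg("too few distinct x values for the requested break count",
                 "caudseg_unfittable_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  interior <- x[x > min(x) & x < max(x)]
  psi0 <- if (!is.null(starts)) sort(as.numeric(starts)) else
    unname(quantile(interior, seq_len(n_breaks) / (n_breaks + 1), names = FALSE))
  if (length(psi0) != n_breaks) {
    stop_caudseg("starts must supply one position per break",
                 "caudseg_validation_error")
  }

  try_iter <- function(xx, yy, st) {
    tryCatch(.seg_iterate(xx, yy, st, max_iter, tol), caudseg_error = function(e) NULL)
  }

  # deterministic multi-start: the central quantile grid plus shifted grids,
  # guarding against local optima of the non-convex RSS surface
  start_set <- list(psi0)
  if (is.null(starts)) {
    for (shift in c(-0.2, 0.2)) {
      probs <- pmin(pmax(seq_len(n_breaks) / (n_breaks + 1) + shift, 0.05), 0.95)
      start_set <- c(start_set, list(unname(quantile(interior, probs, names = FALSE))))
    }
  }
  start_set <- c(start_set, extra_starts %||% list())
  best <- NULL
  for (st in start_set) {
    st <- sort(as.numeric(st))
    if (length(st) != n_breaks) next
    if (n_breaks > 1 && any(diff(st) < .min_psi_gap(x))) next
    cand <- try_iter(x, y, st)
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss - 1e-12)) best <- cand
  }
  if (n_boot > 0) {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      st <- if (!is.null(best)) best$psi else psi0
      bf <- try_iter(x[idx], y[idx], st)
      if (is.null(bf)) next
      refit <- try_iter(x, y, bf$psi)
      if (is.null(refit)) next
      if (is.null(best) || refit$rss < best$rss - 1e-12) best <- refit
    }
  }
  if (is.null(best)) {
    stop_caudseg(sprintf("segmented model with %d break(s) could not be fitted",
                         n_breaks), "caudseg_unfittable_error")
  }
  # local polish of the winning break points, then one finalisation pass for
  # the constrained coefficients and the break-point standard errors
  psi_polished <- .seg_polish(x, y, best$psi)
  final <- tryCatch(
    .seg_finalize(x, y, psi_polished, best$converged, best$iter),
    caudseg_error = function(e) NULL
  )
  if (is.null(final) || final$rss > best$rss + 1e-12) {
    final <- .seg_finalize(x, y, best$psi, best$converged, best$iter)
  }
  best <- final
  n_coef <- 2L + 2L * n_breaks
  structure(list(
    n_breaks = n_breaks,
    breakpoints = best$psi,
    breakpoint_se = best$se_psi,
    intercept = best$coef[1],
    base_slope = best$coef[2],
    slope_changes = best$coef[3:(2 + n_breaks)],
    rss = best$rss,
    n = n,
    n_coef = n_coef,
    aic = aic_gaussian(best$rss, n, n_coef),
    converged = best$converged,
    n_iterations = best$iter,
    fitted = best$fitted,
    x = x, y = y
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("<segmented_fit> %d break(s), n = %d, RSS = %.4g, AIC = %.4g%s\n",
              x$n_breaks, x$n, x$rss, x$aic,
              if (x$converged) "" else " (not converged)"))
  bp <- sprintf("%.2f +/- %.2f", x$breakpoints, x$breakpoint_se)
  cat("  break points:", paste(bp, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the fitted piecewise-linear mean function
#'
#' @param object A `segmented_fit`.
#' @param newdata Optional numeric vector of vertebra numbers (defaults to the
#'   fitting positions).
#' @param ... Unused.
#' @return Predicted centrum lengths (mm).
#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else as.numeric(newdata)
  mu <- object$intercept + object$base_slope * xx
  for (j in seq_len(object$n_breaks)) {
    mu <- mu + object$slope_changes[j] * pmax(xx - object$breakpoints[j], 0)
  }
  mu
}

#' Fit segmented models along an increasing break-count path
#'
#' Fits segmented candidates for `n_breaks = 1..max_breaks`, passing each
#' candidate the previous candidate's solution (augmented with one extra knot
#' in the widest inter-knot gap) as an additional start, so that the
#' best-found RSS is non-increasing in the break count. Unfittable candidates
#' are recorded as `NULL`.
#'
#' @inheritParams fit_segmented
#' @param max_breaks Largest break count to try (1 to 4).
#' @param seeds Optional integer vector of per-candidate seeds (length
#'   `max_breaks`); defaults to `seed + 0:(max_breaks-1)` when `seed` given.
#' @return A list of length `max_breaks` of `segmented_fit` or `NULL`.
#' @export
fit_segmented_path <- function(x, y, max_breaks = 4, n_boot = 50, max_iter = 10,
                               seed = NULL, seeds = NULL, tol = 1e-4) {
  max_breaks <- as.integer(max_breaks)
  stopifnot(max_breaks >= 1L, max_breaks <= 4L)
  if (is.null(seeds) && !is.null(seed)) seeds <- as.integer(seed) + 0:(max_breaks - 1L)
  fits <- vector("list", max_breaks)
  prev <- NULL
  for (k in seq_len(max_breaks)) {
    extra <- list()
    if (!is.null(prev)) {
      psi_prev <- prev$breakpoints
      knots <- sort(c(min(x), psi_prev, max(x)))
      gap <- which.max(diff(knots))
      extra <- list(sort(c(psi_prev, (knots[gap] + knots[gap + 1]) / 2)))
    }
    fits[k] <- list(tryCatch(
      fit_segmented(x, y, n_breaks = k, n_boot = n_boot, max_iter = max_iter,
                    seed = if (!is.null(seeds)) seeds[k] else NULL, tol = tol,
                    extra_starts = extra),
      caudseg_error = function(e) NULL
    ))
    if (!is.null(fits[[k]])) {
      # keep the RSS path monotone: a k-break fit can never beat being handed
      # the (k-1)-break solution plus a free knot, so take the better of the two
      if (!is.null(prev) && fits[[k]]$rss > prev$rss * (1 + 1e-8)) {
        alt <- tryCatch(
          fit_segmented(x, y, n_breaks = k, starts = extra[[1]], n_boot = 0,
                        max_iter = max_iter, tol = tol),
          caudseg_error = function(e) NULL
        )
        if (!is.null(alt) && alt$rss < fits[[k]]$rss) fits[k] <- list(alt)
      }
      if (!is.null(fits[[k]])) prev <- fits[[k]]
    }
  }
  fits
}

#' Discontinuous two-regime regression
#'
#' Models the series as two separate lines: the vertebrae are split into a
#' proximal and a distal group at `split` (the first vertebra number of the
#' distal group) and `y` is regressed on group, `x`, and their interaction,
#' i.e. a separate intercept and slope per group (4 coefficients). When
#' `split` is not given, every admissible split (at least 3 points and 2
#' distinct positions per group) is tried and the split minimising the RSS is
#' chosen; ties go to the smallest split position.
#'
#' @param x,y Numeric vectors: vertebra numbers and centrum lengths (mm).
#' @param split Optional split position (first vertebra of the distal group).
#' @return An object of class `discontinuous_fit`: `split_position`,
#'   `intercepts` (proximal, distal), `slopes` (proximal, distal), `rss`,
#'   `n`, `aic` (`n_coef = 4`).
#' @export
fit_discontinuous <- function(x, y, split = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 6) {
    stop_caudseg("fit_discontinuous needs >= 6 paired observations",
                 "caudseg_validation_error")
  }
  rss_at <- function(s) {
    lo <- x < s; hi <- !lo
    if (sum(lo) < 3 || sum(hi) < 3 ||
        length(unique(x[lo])) < 2 || length(unique(x[hi])) < 2) return(NA_real_)
    f1 <- lm.fit(cbind(1, x[lo]), y[lo])
    f2 <- lm.fit(cbind(1, x[hi]), y[hi])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }
  if (is.null(split)) {
    cand <- sort(unique(x))
    rsses <- vapply(cand, rss_at, numeric(1))
    if (all(is.na(rsses))) {
      stop_caudseg("no admissible split (need >= 3 points per group)",
                   "caudseg_unfittable_error")
    }
    split <- cand[which.min(rsses)]  # which.min takes the first: smallest split
  } else if (is.na(rss_at(split))) {
    stop_caudseg("requested split is not admissible", "caudseg_unfittable_error")
  }
  lo <- x < split; hi <- !lo
  f1 <- lm.fit(cbind(1, x[lo]), y[lo])
  f2 <- lm.fit(cbind(1, x[hi]), y[hi])
  rss <- sum(f1$residuals^2) + sum(f2$residuals^2)
  structure(list(
    split_position = split,
    intercepts = unname(c(proximal = f1$coefficients[1], distal = f2$coefficients[1])),
    slopes = unname(c(proximal = f1$coefficients[2], distal = f2$coefficients[2])),
    rss = rss, n = n, n_coef = 4L,
    aic = aic_gaussian(rss, n, 4L)
  ), class = "discontinuous_fit")
}

#' @export
print.discontinuous_fit <- function(x, ...) {
  cat(sprintf("<discontinuous_fit> split at vertebra %s (n = %d, RSS = %.4g, AIC = %.4g)\n",
              format(x$split_position), x$n, x$rss, x$aic))
  cat(sprintf("  proximal: y = %.4g %+.4g x;  distal: y = %.4g %+.4g x\n",
              x$intercepts[1], x$slopes[1], x$intercepts[2], x$slopes[2]))
  invisible(x)
}
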