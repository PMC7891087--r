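## Davies test for a non-constant slope: the break point exists only under
## the alternative, so the hinge t statistic is scanned over a grid of
## candidate positions and the maximum is referred to an upper bound on its
## null distribution.

#' Davies test for a non-constant regression slope
#'
#' Tests whether the slope of `y` on `x` changes somewhere in the range of
#' `x`, i.e. whether at least one break point exists. At each candidate
#' position theta on a grid of `k` equally spaced quantiles of `x` (restricted
#' to the 5th-95th percentiles to avoid boundary hinges), the hinge term
#' `(x - theta)_+` is added to the straight-line regression and its t
#' statistic recorded. The test statistic is `M = max |t(theta)|`, and the
#' two-sided p-value uses the Davies upper bound
#' `p = 2 * (P(T > M) + V * exp(-M^2 / 2) / sqrt(8 * pi))`, truncated at 1,
#' where `V` is the total variation `sum |t(theta_{i+1}) - t(theta_i)|` and
#' `T` a t distribution on the residual degrees of freedom. The bound is
#' conservative; a significant result (default gate `alpha = 0.05` in
#' [select_model()]) licenses segmented fitting.
#'
#' @param x,y Numeric vectors: vertebra numbers and centrum lengths (mm).
#' @param k Number of grid points (default 10); reduced, with a message, when
#'   fewer than `k + 2` distinct `x` values are available.
#' @return An object of class `davies_result`: `grid`, `statistics` (signed t
#'   at each grid point), `max_stat`, `best_theta`, `p_value`, `df`,
#'   `degenerate` (flag for constant `y`).
#' @examples
#' x <- 1:40
#' y <- ifelse(x <= 20, 60 - 2 * x, 20 + 2 * (x - 20)) + rnorm(40, 0, 0.1)
#' davies_test(x, y)$p_value
#' @export
davies_test <- function(x, y, k = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 8 || length(y) != n) {
    stop_caudseg("davies_test needs >= 8 paired observations",
                 "caudseg_validation_error")
  }
  n_distinct <- length(unique(x))
  if (n_distinct < k + 2) {
    k_new <- max(2L, n_distinct - 2L)
    message(sprintf("davies_test: grid reduced from %d to %d points (only %d distinct x)",
                    k, k_new, n_distinct))
    k <- k_new
  }
  if (sd(y) == 0) {
    return(structure(list(
      grid = numeric(), statistics = numeric(), max_stat = 0,
      best_theta = NA_real_, p_value = 1, df = n - 3L, degenerate = TRUE
    ), class = "davies_result"))
  }
  theta <- unique(unname(quantile(x, seq(0.05, 0.95, length.out = k))))
  theta <- theta[theta > min(x) & theta < max(x)]
  if (length(theta) < 2) {
    stop_caudseg("fewer than 2 admissible grid positions", "caudseg_validation_error")
  }
  df <- n - 3L
  tstat <- rep(NA_real_, length(theta))
  for (i in seq_along(theta)) {
    X <- cbind(1, x, pmax(x - theta[i], 0))
    qx <- qr(X)
    if (qx$rank < 3L) next
    cf <- qr.coef(qx, y)
    res <- y - X %*% cf
    sigma2 <- sum(res^2) / df
    se <- sqrt(diag(chol2inv(qr.R(qx)) * sigma2))[3]
    if (is.finite(se) && se > 0) tstat[i] <- cf[3] / se
  }
  keep <- is.finite(tstat)
  theta <- theta[keep]; tstat <- tstat[keep]
  if (length(theta) < 2) {
    stop_caudseg("Davies statistic undefined on the whole grid",
                 "caudseg_unfittable_error")
  }
  M <- max(abs(tstat))
  V <- sum(abs(diff(tstat)))
  p <- 2 * (pt(M, df, lower.tail = FALSE) + V * exp(-M^2 / 2) / sqrt(8 * pi))
  structure(list(
    grid = theta, statistics = tstat, max_stat = M,
    best_theta = theta[which.max(abs(tstat))],
    p_value = min(1, p), df = df, degenerate = FALSE
  ), class = "davies_result")
}

#' @export
print.davies_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<davies_result> degenerate (constant response), p = 1\n")
  } else {
    cat(sprintf("<davies_result> M = %.3f at theta = %.2f over %d grid points, p = %.4g\n",
                x$max_stat, x$best_theta, length(x$grid), x$p_value))
  }
  invisible(x)
}
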