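test_that("fit_linear recovers an exact line and matches the closed-form slope", {
  f <- fit_linear(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_lt(f$rss, 1e-20)

  set.seed(11)
  x <- sort(runif(40, 1, 60)); y <- 30 - 0.4 * x + rnorm(40, 0, 2)
  f <- fit_linear(x, y)
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(f$slope, slope_oracle, tolerance = 1e-12)
  expect_error(fit_linear(rep(3, 5), 1:5), class = "caudseg_singular_error")
})

test_that("the Gaussian AIC convention agrees with stats::AIC on lm fits", {
  set.seed(21)
  x <- 1:25; y <- 20 - 0.5 * x + rnorm(25)
  f <- fit_linear(x, y)
  expect_equal(f$aic, AIC(lm(y ~ x)), tolerance = 1e-10)
  expect_equal(f$log_likelihood, as.numeric(logLik(lm(y ~ x))), tolerance = 1e-10)
})

test_that("a noiseless kink is recovered exactly", {
  d <- make_kink(n = 30, kink = 10)
  f <- fit_segmented(d$x, d$y, n_breaks = 1, seed = 1)
  expect_equal(f$breakpoints, 10, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_true(f$converged)
  expect_gt(f$breakpoint_se, 0)
})

test_that("one-break fits match the fine-grid two-segment oracle", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(20:60, 1)
    kink <- runif(1, 0.25 * n, 0.75 * n)
    sl <- c(runif(1, -2, -0.5), runif(1, 0.3, 1.5))
    y <- kink_profile(seq_len(n), 40, kink, sl) + rnorm(n, 0, 1)
    f <- fit_segmented(seq_len(n), y, 1, seed = i)
    oracle <- grid_two_segment_rss(seq_len(n), y)
    expect_lte(f$rss, oracle + 1e-6 * max(1, oracle))
  }
})

test_that("the RSS path is monotone in the break count and fits reconstruct their data", {
  set.seed(41)
  sp <- three_break_series_spec(60, seed = 5)
  s <- generate_series(sp)
  fits <- fit_segmented_path(s$positions, s$lengths, max_breaks = 4, seed = 9)
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-8 * rss[-4]))
  for (f in fits) {
    expect_lt(max(abs(predict(f) - f$fitted)), 1e-8)
    expect_true(all(diff(f$breakpoints) > 0))
    expect_true(all(f$breakpoints > min(s$positions) &
                      f$breakpoints < max(s$positions)))
  }
})

test_that("segmented fits are bit-identical under a fixed seed", {
  sp <- dinosaur_series_spec(50, seed = 77)
  s <- generate_series(sp)
  f1 <- fit_segmented(s$positions, s$lengths, 2, seed = 123)
  f2 <- fit_segmented(s$positions, s$lengths, 2, seed = 123)
  expect_identical(f1, f2)
})

test_that("unfittable candidates raise the dedicated error class", {
  expect_error(fit_segmented(1:7, rnorm(7), 3), class = "caudseg_validation_error")
  # constant response: slope change coefficient is numerically zero
  expect_error(fit_segmented(1:20, rep(5, 20), 1, n_boot = 0),
               class = "caudseg_unfittable_error")
})

test_that("discontinuous fit recovers a constructed two-regime series", {
  x <- 1:24
  y <- ifelse(x < 11, 10 - 0.5 * x, 40 - 0.5 * x)  # parallel lines, jump at 11
  f <- fit_discontinuous(x, y)
  expect_equal(f$split_position, 11)
  expect_equal(unname(f$slopes[1]), unname(f$slopes[2]), tolerance = 1e-10)
  expect_lt(f$rss, 1e-18)
})

test_that("automatic split equals the exhaustive-split oracle", {
  set.seed(51)
  x <- 1:40
  y <- ifelse(x < 17, 28 - 1.2 * x, 55 - 0.4 * x) + rnorm(40, 0, 1.5)
  f <- fit_discontinuous(x, y)
  # independent exhaustive search via lm() per group
  rss_at <- function(s) {
    lo <- x < s
    if (sum(lo) < 3 || sum(!lo) < 3) return(NA_real_)
    sum(resid(lm(y[lo] ~ x[lo]))^2) + sum(resid(lm(y[!lo] ~ x[!lo]))^2)
  }
  cand <- sort(unique(x))
  oracle_rss <- vapply(cand, rss_at, numeric(1))
  expect_equal(f$split_position, cand[which.min(oracle_rss)])
  expect_equal(f$rss, min(oracle_rss, na.rm = TRUE), tolerance = 1e-10)
  expect_equal(f$aic, aic_gaussian(f$rss, 40, 4))
})
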