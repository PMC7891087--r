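test_that("nearest-break distance arithmetic", {
  expect_equal(nearest_break_distance(c(12.0, 45.8), 12), 0)
  expect_equal(nearest_break_distance(5, 5), 0)
  expect_equal(nearest_break_distance(c(3, 9), 7), 2)
  expect_error(nearest_break_distance(numeric(0), 5),
               class = "caudseg_validation_error")
  expect_error(nearest_break_distance(3, NA), class = "caudseg_validation_error")
})

test_that("Monte-Carlo null mean matches exhaustive enumeration", {
  # independent oracle: enumerate all single placements on 2..39
  pos <- 2:39
  exact1 <- mean(abs(pos - 20))
  expect_equal(expected_null_distance(40, 1, 20), exact1, tolerance = 1e-12)

  reps <- 20000
  mc <- null_mean_distance(40, 1, 20, reps = reps, seed = 4)
  se <- sd(abs(pos - 20)) / sqrt(reps)
  expect_lt(abs(mc - exact1), 3 * se)
  mc_large <- null_mean_distance(40, 1, 20, reps = 200000, seed = 7)
  expect_lt(abs(mc_large - exact1) / exact1, 0.005)

  # two breaks: enumerate all C(38, 2) placements
  pairs <- combn(pos, 2)
  exact2 <- mean(pmin(abs(pairs[1, ] - 20), abs(pairs[2, ] - 20)))
  expect_equal(expected_null_distance(40, 2, 20), exact2, tolerance = 1e-12)
  mc2 <- null_mean_distance(40, 2, 20, reps = reps, seed = 5)
  expect_lt(abs(mc2 - exact2) / exact2, 0.05)
})

test_that("an extreme transition point has a larger null mean than a central one", {
  expect_gt(expected_null_distance(40, 1, 1), expected_null_distance(40, 1, 20))
  expect_gt(null_mean_distance(40, 1, 1, reps = 5000, seed = 6),
            null_mean_distance(40, 1, 20, reps = 5000, seed = 6))
})

test_that("two independent seeds agree within Monte-Carlo error", {
  exact <- expected_null_distance(50, 2, 17)
  reps <- 4000
  a <- null_mean_distance(50, 2, 17, reps = reps, seed = 11)
  b <- null_mean_distance(50, 2, 17, reps = reps, seed = 12)
  # distances are bounded by the series length; a crude SD bound suffices
  se_bound <- 50 / sqrt(reps)
  expect_lt(abs(a - b), 4 * se_bound)
  expect_lt(abs(a - exact), 4 * se_bound)
})

test_that("the exact binomial p matches term-by-term summation and closed forms", {
  sum_oracle <- function(k, n) {
    lower <- sum(dbinom(0:k, n, 0.5))
    upper <- sum(dbinom(k:n, n, 0.5))
    min(1, 2 * min(lower, upper))
  }
  for (case in list(c(18, 25), c(7, 25), c(13, 25), c(0, 10), c(40, 61))) {
    expect_equal(proximity_binomial_p(case[1], case[2]),
                 sum_oracle(case[1], case[2]), tolerance = 1e-12)
  }
  expect_equal(proximity_binomial_p(25, 25), 2 * 0.5^25, tolerance = 1e-15)
  expect_equal(proximity_binomial_p(18, 25), binom.test(18, 25)$p.value,
               tolerance = 1e-12)
})

test_that("proximity test counts strict inequalities and excludes ineligible specimens", {
  results <- list(
    fake_selection("A", breakpoints = 12, n_vertebrae = 40, transition_point = 12),
    fake_selection("B", breakpoints = c(5, 30), n_vertebrae = 45, transition_point = 31),
    structure(list(specimen_id = "LIN", chosen = "linear",
                   chosen_fit = list(), chosen_n_breaks = 0L,
                   n_vertebrae = 30, transition_point = 10),
              class = "model_selection_result"),
    fake_selection("NOTP", breakpoints = 8, n_vertebrae = 30,
                   transition_point = NA_real_)
  )
  prox <- proximity_test(results, reps = 500, seed = 42)
  expect_equal(prox$n_total, 2)
  expect_setequal(prox$excluded, c("LIN", "NOTP"))
  expect_true(prox$per_specimen$closer[prox$per_specimen$specimen_id == "A"])
  expect_equal(prox$binomial_p,
               proximity_binomial_p(prox$n_closer, prox$n_total))
  expect_error(proximity_test(results[3:4], reps = 100),
               class = "caudseg_validation_error")
})

test_that("transition points generated at true breaks make nearly every specimen closer than chance", {
  co <- generate_cohort(cohort_spec(n_specimens = 12, noise_frac = 0.01,
                                    n_vertebrae_range = c(40, 70), seed = 314))
  res <- screen_batch(co$series, seed = 314)
  prox <- proximity_test(res, reps = 500, seed = 314)
  expect_gte(prox$n_closer / prox$n_total, 0.9)
  expect_lt(prox$binomial_p, 0.05)
})
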