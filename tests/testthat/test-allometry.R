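make_records <- function(n = 23, seed = 101, correlation = 0) {
  co <- generate_cohort(cohort_spec(n_specimens = n, seed = seed,
                                    correlation = correlation))
  co$specimens
}

test_that("femur-scaled ratios are computed per specimen", {
  rec <- data.frame(specimen_id = c("SCUT", "EQ", "NOSS"),
                    taxon = c("Scutellosaurus", "T2", "T3"),
                    femur_mm = c(82, 100, 90),
                    snout_sacrum_mm = c(NA, 250, 200),
                    tail_mm = c(721.6, 100, NA),
                    locomotor_class = "biped",
                    largest_of_species = TRUE, stringsAsFactors = FALSE)
  samples <- build_samples(rec)
  expect_equal(round(samples$tail_femur_ratio[1], 1), 8.8)
  expect_equal(samples$tail_femur_ratio[2], 1.0)
  # specimens missing one ratio are kept but cannot enter the regression
  expect_equal(nrow(samples), 3)
  expect_true(is.na(samples$snout_sacrum_femur_ratio[1]))

  rec$femur_mm[2] <- NA
  expect_warning(build_samples(rec), "without femur")
})

test_that("the F statistic matches the anova route and equals t squared", {
  samples <- build_samples(make_records())
  fit <- allometry_regress(samples, "all")
  keep <- !is.na(samples$tail_femur_ratio) & !is.na(samples$snout_sacrum_femur_ratio)
  lmfit <- lm(snout_sacrum_femur_ratio ~ tail_femur_ratio, data = samples[keep, ])
  expect_equal(fit$f_statistic, anova(lmfit)[1, "F value"], tolerance = 1e-10)
  tval <- summary(lmfit)$coefficients[2, "t value"]
  expect_equal(fit$f_statistic, tval^2, tolerance = 1e-10)
  expect_equal(fit$df, c(1L, fit$n - 2L))
})

test_that("a perfect relationship gives a huge F; permuted data rejects at the nominal rate", {
  samples <- build_samples(make_records())
  perfect <- samples
  perfect$snout_sacrum_femur_ratio <- perfect$tail_femur_ratio
  f <- suppressWarnings(allometry_regress(perfect, "all"))  # exact fit by design
  expect_gt(f$f_statistic, 1e10)
  expect_lt(f$p_value, 1e-12)

  set.seed(202)
  n_rep <- 300
  rej <- 0
  base <- samples[!is.na(samples$snout_sacrum_femur_ratio), ]
  for (i in seq_len(n_rep)) {
    shuffled <- base
    shuffled$snout_sacrum_femur_ratio <- sample(base$snout_sacrum_femur_ratio)
    if (allometry_regress(shuffled, "all")$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.05)
})

test_that("scaling every femur leaves ratios-based inference unchanged", {
  rec <- make_records(seed = 103)
  f1 <- allometry_regress(build_samples(rec), "all")
  rec2 <- rec
  rec2$femur_mm <- rec2$femur_mm * 3
  rec2$snout_sacrum_mm <- rec2$snout_sacrum_mm * 3
  rec2$tail_mm <- rec2$tail_mm * 3
  f2 <- allometry_regress(build_samples(rec2), "all")
  expect_equal(f1$f_statistic, f2$f_statistic, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
})

test_that("locomotor subsets and the largest-individual restriction filter correctly", {
  rec <- make_records(n = 40, seed = 104)
  samples <- build_samples(rec)
  bip <- allometry_regress(samples, "bipeds")
  expect_lte(bip$n, sum(samples$locomotor_class == "biped"))
  bf <- allometry_regress(samples, "bipeds_facultative")
  expect_gte(bf$n, bip$n)

  # duplicate every taxon at a smaller femur; largest_only must drop the copies
  rec_dup <- rec
  rec_dup$specimen_id <- paste0(rec$specimen_id, "b")
  rec_dup$femur_mm <- rec$femur_mm * 0.5
  both <- rbind(rec, rec_dup)
  # the half-femur copies double some ratios beyond the sanity band: expected
  samples_both <- suppressWarnings(build_samples(both))
  fit_l <- allometry_regress(samples_both, "largest_only")
  fit_all_orig <- allometry_regress(build_samples(rec), "all")
  expect_equal(fit_l$n, fit_all_orig$n)
  expect_equal(fit_l$f_statistic, fit_all_orig$f_statistic, tolerance = 1e-10)

  tiny <- samples[1:3, ]
  expect_error(allometry_regress(tiny, "quadrupeds"), "quadrupeds",
               class = "caudseg_validation_error")
})

test_that("intervals fan out from the mean ratio and collapse at zero residual variance", {
  samples <- build_samples(make_records(seed = 105))
  fit <- allometry_regress(samples, "all")
  xs <- fit$x_mean + c(0, 1, 2, 4)
  widths <- vapply(xs, function(x0) {
    iv <- predict_interval(fit, x0, femur_mm = 100)
    iv["upper"] - iv["lower"]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  # prediction intervals are wider than mean-response intervals
  ivp <- predict_interval(fit, fit$x_mean, 100, type = "prediction")
  ivc <- predict_interval(fit, fit$x_mean, 100, type = "confidence")
  expect_gt(ivp["upper"] - ivp["lower"], ivc["upper"] - ivc["lower"])

  collinear <- samples
  collinear$snout_sacrum_femur_ratio <- 1 + 0.2 * collinear$tail_femur_ratio
  f0 <- suppressWarnings(allometry_regress(collinear, "all"))  # exact fit by design
  iv <- predict_interval(f0, 5, 100)
  expect_equal(unname(iv["lower"]), unname(iv["upper"]), tolerance = 1e-6)
  expect_equal(unname(iv["lower"]), attr(iv, "point"), tolerance = 1e-6)

  expect_warning(predict_interval(fit, 100, 100), "outside the observed range")
})
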