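make_pipeline_inputs <- function(n = 6, seed = 11) {
  co <- generate_cohort(cohort_spec(n_specimens = n, seed = seed))
  series_file <- tempfile(fileext = ".csv")
  specimens_file <- tempfile(fileext = ".csv")
  write_series_table(co$series, series_file)
  write.csv(co$specimens, specimens_file, row.names = FALSE, na = "")
  list(series = series_file, specimens = specimens_file)
}

test_that("run_config validates its fields", {
  cfg <- run_config(seed = 9)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$n_boot, 50L)
  expect_error(run_config(alpha = 1.2), class = "caudseg_validation_error")
  expect_error(run_config(reps = 0), class = "caudseg_validation_error")
})

test_that("cmd_fit reports a fit, errors helpfully on unknown ids, and is byte-stable", {
  inputs <- make_pipeline_inputs(n = 3, seed = 12)
  expect_error(cmd_fit(inputs$series, "NOPE"), "SYN001",
               class = "caudseg_validation_error")

  out1 <- tempfile(fileext = ".json")
  out2 <- tempfile(fileext = ".json")
  cfg <- run_config(seed = 4)
  rep1 <- cmd_fit(inputs$series, "SYN001", cfg, out = out1)
  cmd_fit(inputs$series, "SYN001", cfg, out = out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_equal(rep1$selection$specimen_id, "SYN001")
  expect_true(rep1$selection$fit$model %in% c("linear", "segmented", "discontinuous"))

  png_file <- tempfile(fileext = ".png")
  cmd_fit(inputs$series, "SYN001", cfg, plot_file = png_file)
  expect_true(file.size(png_file) > 0)
})

test_that("cmd_pipeline emits all three report sections with provenance", {
  inputs <- make_pipeline_inputs(n = 6, seed = 13)
  out <- tempfile(fileext = ".json")
  rep <- cmd_pipeline(inputs$series, inputs$specimens, run_config(seed = 2),
                      out = out)
  expect_named(rep, c("config", "inputs", "model_selection", "proximity",
                      "allometry", "n_warnings"))
  expect_length(rep$model_selection, 6)
  expect_true(rep$proximity$n_total >= 1)
  expect_true("all" %in% names(rep$allometry))
  expect_true(all(nchar(unlist(rep$inputs)) == 32))  # md5 provenance
  parsed <- jsonlite::read_json(out)
  expect_equal(parsed$proximity$n_total, rep$proximity$n_total)
})

test_that("changing the master seed moves only stochastic quantities", {
  inputs <- make_pipeline_inputs(n = 5, seed = 14)
  r1 <- cmd_pipeline(inputs$series, inputs$specimens, run_config(seed = 1))
  r2 <- cmd_pipeline(inputs$series, inputs$specimens, run_config(seed = 2))
  # deterministic: OLS-based allometry and the linear AICs
  expect_equal(r1$allometry$all$f_statistic, r2$allometry$all$f_statistic)
  lin1 <- vapply(r1$model_selection, function(m) m$aic$linear, numeric(1))
  lin2 <- vapply(r2$model_selection, function(m) m$aic$linear, numeric(1))
  expect_equal(lin1, lin2)
  # stochastic: the randomized null means are free to differ
  expect_false(identical(r1$proximity$per_specimen$null_mean_distance,
                         r2$proximity$per_specimen$null_mean_distance))
})

test_that("proximity CSV export mirrors the per-specimen quantities", {
  results <- list(
    fake_selection("A", 12, 40, 12),
    fake_selection("B", c(5, 30), 45, 20)
  )
  prox <- proximity_test(results, reps = 200, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_proximity_csv(prox, path)
  back <- read.csv(path)
  expect_equal(back$specimen_id, c("A", "B"))
  expect_equal(back$actual_distance, prox$per_specimen$actual_distance)
})

test_that("the command-line wrapper ships with the package", {
  cli <- system.file("cli", "caudseg", package = "caudseg")
  expect_true(nzchar(cli))
  first <- readLines(cli, n = 1)
  expect_match(first, "Rscript")
})
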