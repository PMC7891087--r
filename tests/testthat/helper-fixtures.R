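# Fixtures are built in code: small CSVs written to tempfiles, and
# deterministic synthetic series with known break structure.

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# continuous piecewise-linear mean profile
kink_profile <- function(x, start, breaks, slopes) {
  mu <- start + slopes[1] * (x - 1)
  for (j in seq_along(breaks)) {
    mu <- mu + (slopes[j + 1] - slopes[j]) * pmax(x - breaks[j], 0)
  }
  mu
}

# symmetric V-shaped kink at x = kink (slopes -1 then +1)
make_kink <- function(n = 30, kink = 10, start = 30) {
  x <- seq_len(n)
  list(x = x, y = kink_profile(x, start, kink, c(-1, 1)))
}

# exhaustive two-segment OLS RSS on a 0.01-step grid of break candidates;
# independent of the package fitting path
grid_two_segment_rss <- function(x, y, step = 0.01) {
  lo <- min(x) + step
  hi <- max(x) - step
  best <- Inf
  for (psi in seq(lo, hi, by = step)) {
    X <- cbind(1, x, pmax(x - psi, 0))
    rss <- sum(.lm.fit(X, y)$residuals^2)
    if (rss < best) best <- rss
  }
  best
}

# piecewise profiles with 0-4 true breaks at the 60-vertebra reference,
# used for break-count recovery experiments
recovery_spec <- function(true_breaks, n = 60, noise_frac = 0.05, seed = NULL) {
  switch(as.character(true_breaks),
    "0" = series_spec(n, numeric(0), -0.45, start_length = 40,
                      noise_sd = noise_frac * mean(40 - 0.45 * (seq_len(n) - 1)),
                      seed = seed),
    "1" = {
      br <- round(0.4 * n); sl <- c(-1.0, -0.1)
      mu <- kink_profile(seq_len(n), 40, br, sl)
      series_spec(n, br, sl, 40, noise_sd = noise_frac * mean(mu), seed = seed)
    },
    "2" = dinosaur_series_spec(n, noise_frac, seed = seed),
    "3" = three_break_series_spec(n, noise_frac, seed = seed),
    "4" = {
      br <- round(c(0.15, 0.3, 0.5, 0.7) * n)
      sl <- c(-2, 1.5, -0.2, -1.2, 0.3) * 60 / n
      mu <- kink_profile(seq_len(n), 40, br, sl)
      series_spec(n, br, sl, 40, noise_sd = noise_frac * mean(mu), seed = seed)
    }
  )
}

# minimal stand-in for a model_selection_result, for simulations that do not
# need the fitting machinery
fake_selection <- function(specimen_id, breakpoints, n_vertebrae, transition_point) {
  structure(list(
    specimen_id = specimen_id,
    chosen = "segmented",
    chosen_fit = list(breakpoints = breakpoints),
    chosen_n_breaks = length(breakpoints),
    n_vertebrae = n_vertebrae,
    transition_point = transition_point
  ), class = "model_selection_result")
}
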