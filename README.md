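# caudseg

Break-point analysis of serial measurements along vertebrate tails.

Dinosaur tails are measured one vertebra at a time: vertebra number against
anteroposterior centrum length (mm). These series rarely follow one straight
taper — a typical tail has a short proximal run of short centra, a region of
longer centra, and a long tapering distal series — and the boundaries
between regimes carry anatomical meaning, because the lateral processes
(which anchor the caudofemoral musculature) end at a *transition point*
partway down the tail. caudseg asks, for each specimen, where centrum
length changes regime; across specimens, whether those changes sit closer
to the transition point than chance allows; and, at the whole-animal scale,
whether tail length predicts body size at all.

The package is aimed at comparative morphologists working with serial
skeletal measurements, but the machinery is generic: any ordered
series with suspected slope changes fits.

## The models

**Segmented (broken-stick) regression.** For vertebra number $x$ and
centrum length $y$, with $K$ break points,

$$E[y] = \beta_0 + \beta_1 x + \sum_{j=1}^{K} \delta_j\,(x - \psi_j)_+ ,$$

fitted by iterative linearization (the gap-coefficient update
$\psi_j \leftarrow \psi_j + \hat\gamma_j/\hat\delta_j$) with quantile
starting values, 50 bootstrap restarts and a maximum of 10 iterations,
plus step-halving and a local polish for the non-smooth RSS surface.
Break-point standard errors are $SE(\hat\gamma_j)/|\hat\delta_j|$.

**Gate, then choose.** Since $\psi$ exists only under the alternative, a
Davies test (maximum hinge |t| over a 10-point grid, with the
$p \le 2[P(T>M) + V e^{-M^2/2}/\sqrt{8\pi}]$ bound) decides whether any
break exists at $\alpha = 0.05$. If yes, candidates with 1-4 breaks
compete on the Gaussian ML AIC
($n\log(2\pi\,\mathrm{RSS}/n) + n + 2(p+1)$, break points counted as
parameters); ties go to fewer breaks. If no, the model is linear, with an
optional discontinuous two-regime alternative (separate line per group,
exhaustive split search) for tails with a genuine jump.

**Proximity randomization test.** Per specimen, the distance from the
transition point to the nearest fitted break is compared with the mean of
1,000 random placements of the same number of breaks on the same series;
the count of specimens strictly closer than their null mean goes into a
two-sided exact binomial test against 0.5.

**Femur-scaled allometry.** Tail length and snout-sacrum length are each
scaled by the femur of the individual they were measured from, and the
snout-sacrum ratio is regressed on the tail ratio ($F = t^2$ on
$(1, n-2)$ df), overall, within locomotor classes, and restricted to the
largest individual per taxon; `predict_interval()` turns the fit into a
per-specimen body-size interval (prediction interval by default).

A synthetic-data generator (`generate_series()`, `generate_cohort()`)
produces caudal series and whole cohorts with known break structure,
transition points tied to breaks, and controlled correlation between the
femur-scaled ratios, so the full pipeline is testable without specimen
data.

## Worked example

```r
library(caudseg)

co <- generate_cohort(cohort_spec(n_specimens = 10, seed = 42))
write_series_table(co$series, "series.csv")
write.csv(co$specimens, "specimens.csv", row.names = FALSE, na = "")

report <- cmd_pipeline("series.csv", "specimens.csv", run_config(seed = 7))
```

On this cohort the run prints, via the report object:

```
report$model_selection[["SYN001"]]$chosen      # "segmented"
report$model_selection[["SYN001"]]$davies$p_value  # 1.29e-08
report$proximity$n_closer                      # 10 (of 10), binomial p = 0.00195
report$allometry$all$f_statistic               # 0.00755 on df (1, 8), p = 0.933
```

Reading: every specimen's Davies gate rejects a straight line (p ~ 1e-8),
so segmented models are fitted and chosen by AIC — SYN001 gets break
points at 14.0, 27.1, 34.0 and 64.1, the second sitting on its transition
point at vertebra 27. All 10 specimens have their nearest break closer to
the transition point than random placement predicts (exact binomial
p = 0.002), while the allometric F of 0.008 (p = 0.93) correctly finds no
relation between femur-scaled tail length and body size in a cohort
generated with zero correlation.

Per-specimen fits, with the fitted segments, break points ± SE and the
transition-point arrow, come from `cmd_fit(..., plot_file = "fit.png")`.

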