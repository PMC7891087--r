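---
title: "Break-point analysis of caudal vertebral series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Break-point analysis of caudal vertebral series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caudseg)
```

## The problem

A tetrapod tail is a serial structure: one response value (the
anteroposterior centrum length, in mm) per vertebra number. In many
dinosaurs this series is not a simple taper. A typical profile has a short
proximal run of short centra, a region of longer centra -- often containing
the longest centra in the tail -- and then a long, gradually tapering distal
series. The boundaries between such regimes are of anatomical interest
because the lateral (transverse) processes, which anchor the caudofemoral
musculature, end at a *transition point* partway down the tail; if centrum
length changes regime near that vertebra, tail shape and tail function are
linked.

caudseg treats each specimen's series as a regression problem with unknown
change points and provides the full inference chain: a gate test for whether
*any* break exists, estimation of 1-4 break points, model choice by AIC, a
two-regime discontinuous alternative, a randomization test relating fitted
breaks to the transition point across specimens, and a femur-scaled
allometric analysis of tail length against snout-sacrum length.

## Segmented regression

For vertebra number $x$ and centrum length $y$, the segmented
(broken-stick) model with $K$ breaks is the continuous piecewise-linear
mean

$$E[y] = \beta_0 + \beta_1 x + \sum_{j=1}^{K} \delta_j (x - \psi_j)_+,$$

with break positions $\psi_1 < \dots < \psi_K$ and slope changes
$\delta_j$. Estimation follows the classical iterative linearization: at
working values $\psi^{(t)}$, `y` is regressed by OLS on the intercept, $x$,
the hinge terms $(x - \psi_j)_+$ and the gap indicators
$-\mathbf{1}\{x > \psi_j\}$; writing $\hat\delta_j$ and $\hat\gamma_j$ for
the hinge and gap coefficients, the update is
$\psi_j \leftarrow \psi_j + \hat\gamma_j / \hat\delta_j$, iterated until the
largest update falls below $10^{-4}$ vertebrae or 10 iterations are reached.
Starting values are the $j/(K+1)$ quantiles of the interior $x$ values, and
each candidate is additionally restarted from $\pm 0.2$-shifted quantile
grids and by 50 case-resampling bootstrap restarts (each bootstrap solution
is re-iterated on the original data and solutions compete on original-data
RSS). Numerical safeguards, all visible in `fit_segmented()`:

* the RSS surface is only piecewise smooth (it has kinks wherever a
  $\psi_j$ crosses a data position), so a step that worsens the RSS is
  halved up to five times, and the best iterate by RSS is the one kept;
* the winning solution receives a coordinate-wise local polish
  (`optimize()` within $\pm 1$ vertebra per break) before standard errors
  are computed;
* a step leaving the data range is clamped once and the fit is marked not
  converged on a second violation;
* a slope change below $10^{-10}$ in magnitude, a rank-deficient design, or
  two breaks collapsing onto each other make the candidate *unfittable*
  (`caudseg_unfittable_error`); model selection discards such candidates
  rather than failing.

Break-point standard errors are the delta-method ratio
$SE(\hat\psi_j) = SE(\hat\gamma_j)/|\hat\delta_j|$ from the final
unconstrained pass; reported coefficients come from the constrained
(zero-gap) fit at the final $\psi$. Determinism: with a given `seed`,
refits are bit-identical; in batch runs each (specimen, break count) pair
gets a seed from a stable string hash so results do not depend on batch
order.

## The Davies gate

Whether a break exists at all is decided before any segmented fit, because
$\psi$ is undefined under the null of a single straight line. At each of
$k = 10$ candidate positions $\theta$ (equally spaced quantiles of $x$
restricted to the 5th-95th percentiles, avoiding boundary hinges), the t
statistic of the added hinge term $(x-\theta)_+$ is computed; with
$M = \max_\theta |t(\theta)|$ and total variation
$V = \sum_i |t(\theta_{i+1}) - t(\theta_i)|$, the two-sided p-value is the
Davies upper bound

$$p = 2\left[\,P(T_{n-3} > M) + V\,\frac{e^{-M^2/2}}{\sqrt{8\pi}}\right]$$

truncated at 1. The bound is conservative (simulated type-I rates on
straight-line data stay at or below the nominal 0.05), which errs on the
side of fitting fewer spurious breaks. The gate level defaults to $\alpha = 0.05$, the
field's convention. The p-value is invariant to affine rescaling of the
response and shifts of the position axis.

## Model selection

When the gate passes, segmented candidates with 1-4 breaks compete on the
Gaussian maximum-likelihood AIC,

$$\mathrm{AIC} = n\log(2\pi\,\mathrm{RSS}/n) + n + 2(p + 1),$$

the same convention as `stats::AIC()` on `lm` objects, with the estimated
break points counted as parameters ($p = 2 + 2K$ for $K$ breaks, and the
error variance as the $+1$). Ties go to fewer breaks (parsimony). The
ceiling of four breaks reflects the short series in real material (some
specimens keep only ~20 vertebrae). The candidates are fitted along an
increasing-$K$ path that hands each candidate the previous solution plus a
free knot as an extra start, which keeps the best-found RSS monotone
non-increasing in $K$. A design decision worth making explicit: once the
gate has passed, the linear model does *not* re-enter the AIC comparison --
the gate already rejected it; sensitivity to this choice can be probed by
setting `alpha` to 1.

When the gate *fails*, the chosen model is linear, except that a
*discontinuous* two-regime model (separate intercept and slope per group,
i.e. group + position + interaction, 4 coefficients; split chosen by
exhaustive RSS search, ties to the smallest split) may be offered with
`allow_discontinuous = TRUE` and wins if it beats the linear AIC. This
mirrors the one known tail type -- an armoured tail with short proximal
centra jumping to a long run of near-constant, much longer centra
supporting a club -- where the series is genuinely discontinuous rather
than kinked, and it is deliberately opt-in: on ordinary tapering tails the
4-coefficient discontinuous model can beat a 2-coefficient line by AIC on
noise alone.

Replicate-measurement congruence (`compare_breakpoint_sets()`) pairs the
break points of two fits of the same tail -- for instance one fitted from
direct measurements and one from photographs -- by order (or by proximity
when counts differ, flagged) and reports, per pair, the distance and
whether one fit's break falls within $z$ standard errors of the other's
($z = 1$ by default).

## The proximity randomization test

Per specimen with $K \ge 1$ fitted breaks and a known transition point
$t$, the observed statistic is the nearest-break distance
$\min_j |\hat\psi_j - t|$ in vertebra units -- the only scale shared across
specimens. The null places $K$ break positions uniformly without
replacement on the interior integer positions $\{2, \dots, n-1\}$ of the
same series, preserving the specimen's fitted complexity and tail length
(1000 randomizations by default; `expected_null_distance()` gives the
exact expectation by summing the survival function, used as the oracle in
the test suite). The specimen counts as "closer than chance" when the
actual distance is *strictly* below the randomized mean, and the
across-specimen count is referred to the two-sided exact binomial test
against 0.5, $p = 2\min(P(X \le k), P(X \ge k))$ truncated at 1. Specimens
whose chosen model is linear, or lacking a transition point, are excluded
and listed.

Two calibration caveats belong to this design and are worth stating
plainly, since the package's own simulations quantify both. First, the
comparison of one draw against a *mean* is not median-unbiased: the
min-distance distribution is right-skewed, so even when transition points
are unrelated to breaks, a specimen falls below its null mean with
probability somewhat above one half, and in our null simulations the
aggregate test rejects at two to three times the nominal rate. Second, the exact
binomial p-value is discrete -- with 25 specimens it puts mass ~0.31 on
$p = 1$ -- so its null distribution is far from uniform at any simulation
size. Interpreted strictly, the aggregate p-value is therefore evidence
against a *stylised* null rather than a calibrated error rate; a
mean-vs-mean or rank-based comparison would calibrate better and is noted
as future work. The transition point itself is arguably a zone rather than
a single vertebra, which further argues for reading small distances
qualitatively.

## Femur-scaled allometry

Tail length and snout-sacrum length are often not measurable on the same
individual, so each is divided by the femur length of the individual it
came from; femur length is the body-size proxy (robust to the distortion
that makes circumference unusable in much published material). The analysis
is the OLS regression of snout-sacrum:femur on tail:femur, with
$F = t^2_{\text{slope}}$ on $(1, n-2)$ degrees of freedom, over all samples
and over locomotor subsets (obligate bipeds; obligate quadrupeds; each
pooled with facultative bipeds -- iguanodontian-grade taxa and
psittacosaurids -- and a largest-individual-per-taxon restriction against
pseudoreplication of multi-specimen species, with the largest individual
identified by femur length). Inference is invariant to a common rescaling
of all measurements, as it should be for a dimensionless analysis.

`predict_interval()` converts the fit into a snout-sacrum length interval
for a new specimen: an interval on the ratio scale at the specimen's
tail:femur ratio, multiplied by its femur length. Both the mean-response
confidence interval and the prediction interval are implemented; the
default is the **prediction interval**, because the scientific use is a
statement about an individual specimen's plausible body size, not about
the conditional mean -- and with the slope near zero and $F \approx 0.1$,
the mean-response band would be misleadingly narrow compared with the
scatter the data actually show. Requests more than 50% outside the
observed ratio range are flagged as extrapolation.

## The synthetic-data generator

`generate_series()` draws a series as a continuous piecewise-linear mean
profile plus i.i.d. Gaussian noise, with optional missing vertebrae
(removed rows, i.e. position gaps -- never zero lengths) and a transition
point tied to a designated break plus an offset. Two presets encode the
profiles the analysis is designed for, both starting at 40 mm at caudal 1:

* `dinosaur_series_spec()`: breaks at 20% and 40% of the series, slopes
  $-2.0 / +1.5 / -0.9$ mm per vertebra at the 60-vertebra reference --
  short-long-tapering;
* `three_break_series_spec()`: breaks at 20%, 40% and 67%, slopes
  $-2.0 / +1.5 / -0.2 / -1.2$ -- the same shape with a near-plateau before
  the final taper.

Slopes are rescaled by $60/n$ for other series lengths so the profile
shape (and positivity) is preserved, and the noise SD defaults to 5% of
the mean profile value -- measurement error of a few percent is realistic
for callipered or photographed centra. Because the distal profile tapers
to a few noise SDs above zero, a rare noise draw can cross zero; centrum
lengths are physically positive, so such a draw is redrawn (the truncation
this induces is negligible at these rates and the pooled residuals pass a
skewness check in the test suite).

`generate_cohort()` adds the specimen level: series lengths uniform on
20-90 vertebrae, tail:femur ratios uniform on 1.2-12.4 (the span observed
across dinosaurs), femur lengths uniform on 80-1200 mm, and each series
rescaled so its summed centrum lengths equal ratio x femur exactly (the
tail-sum identity the importer relies on). Snout-sacrum:femur ratios are
drawn as $2.5 + 0.6\,(r\,z_{\text{tail}} + \sqrt{1-r^2}\,\varepsilon)$
with standard-normal $\varepsilon$, giving a target correlation $r$
(default 0, emulating the observed decoupling of tail length from body
size) around a realistic body-to-femur ratio. What the generator does
*not* emulate: intervertebral discs (excluded from the measurement
protocol), heteroscedastic or autocorrelated measurement error,
taphonomic distortion, and phylogenetic structure among specimens --
passing tests on synthetic cohorts therefore validate the machinery, not
those aspects of real data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on generated data at
sizes the package's own analyses use: 50 random instances against a
0.01-step exhaustive grid oracle for one-break fits; 200 replicates of the
three-break, 60-vertebra, 5%-noise recovery experiment (median per-break
error is required to be at most one vertebra); 120 replicates per true
break count 0-4 for modal AIC recovery; 500 straight-line simulations for
the Davies type-I rate; 500 synthetic 25-specimen cohorts for the
proximity-test null; and 500 23-specimen cohorts for the allometric null
rejection rate. Convergence tolerance is $10^{-4}$ vertebrae; RSS
comparisons use a $10^{-8}$ relative tolerance; the binomial component is
exact. An exact fit ($\mathrm{RSS} = 0$) has $\mathrm{AIC} = -\infty$,
which correctly dominates any noisy alternative.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(n_specimens = 10, seed = 42))
write_series_table(co$series, "series.csv")
write.csv(co$specimens, "specimens.csv", row.names = FALSE, na = "")

report <- cmd_pipeline("series.csv", "specimens.csv", run_config(seed = 7))
report$proximity$n_closer
report$allometry$all$f_statistic
```

## Known limitations

Gaussian homoscedastic errors only; no autocorrelation in the residuals of
a series (adjacent centra were measured independently, but biological
smoothness could induce correlation the model ignores); the proximity
null's calibration caveats above; no hierarchical pooling across specimens
of one taxon; the discontinuous model is limited to two regimes; and AICc
is deliberately not used (the break-count ceiling, the gate, and parsimony
tie-breaking already guard against overfitting short series).
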