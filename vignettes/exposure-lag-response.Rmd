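---
title: "Exposure-lag-response modelling of daily counts with crosslag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-lag-response modelling of daily counts with crosslag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslag)
```

## The problem and the model

Acute conditions with environmental triggers — here the motivating case
is severe Bell's palsy, an idiopathic facial paralysis whose onset has
been linked to weather — produce daily count series in which today's risk
may depend on the exposure history of the previous two weeks, and depend
on it non-linearly. The distributed lag non-linear model (DLNM) handles
both dimensions at once. For daily counts $Y_t$ and exposure $x_t$:

$$\log E(Y_t) = \alpha + \sum_{l=0}^{L}\sum_{j,k} \beta_{jk}\,
R_j(x_{t-l})\,C_k(l) + ns(t;\ df) + \gamma_{dow(t)}$$

The double sum is the *cross-basis*: $R_j$ spans the exposure-response
shape, $C_k$ the lag-response shape, and their tensor combination — a
$v_x \times v_l$ block of columns — parameterises a smooth surface
$f(x, l)$ giving the log relative risk of exposure level $x$ acting $l$
days ago. Estimation is quasi-Poisson: the conditional variance is
$\phi\,\mu$ rather than $\mu$, with $\phi$ estimated from the Pearson
statistic, which is the standard guard against overdispersion in daily
admission counts.

Key assumptions: counts are conditionally independent given the
covariates (no outbreak-style contagion); the population at risk is
constant over the window, so no offset is used; seasonality and secular
trend are captured by a smooth function of time; and the
exposure-lag-response surface is smooth enough to live in the span of a
15-dimensional tensor basis.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maxlag` | 14 days | lag window; two weeks covers the clinically plausible induction period |
| `var_df`, `var_degree` | 3, 2 | exposure basis: quadratic B-spline, dimension 3 |
| `lag_df` | 5 | lag basis: natural cubic spline, dimension 5 (with intercept) |
| `time_df_per_year` | 7 | seasonal/trend spline df per year of data |
| `time_total_df` | unset | fixed alternative to the per-year rule (e.g. 84) |
| `dow`, `dow_ref` | TRUE, Monday | day-of-week indicators and reference level |
| `ci_level` | 0.95 | Wald interval level, two-sided |
| `grid_points` | 100 | uniform exposure grid for the minimum-risk search |
| `joint_model` | FALSE | one model per factor vs. all cross-bases at once |

Knot counts follow the dimension rule (`df - degree - intercept` interior
knots for B-splines, `df - 1 - intercept` for natural cubic splines);
knot *locations* are equally spaced quantiles of the observed exposure
(or of the integer lag sequence), the dominant convention in this
literature. The exposure basis drops its first column
(`intercept = FALSE`) because the model has its own intercept; the lag
basis keeps all columns (`intercept = TRUE`). This is the only
intercept convention under which the default dimensions 3 and 5 are
simultaneously consistent with the knot-count rule and an identifiable
cross-basis.

Two readings of the seasonal-spline dimension coexist in applied work:
"7 df per year" (here `round(7 * n/365.25)`, 78 for an 11.2-year series)
and a fixed `7 * 12 = 84`. Both are supported (`time_df_per_year` vs.
`time_total_df`); the per-year rule is the default and neither is
silently corrected into the other.

## Numerical choices

* **B-spline evaluation** uses the padded knot sequence (boundary knots
  repeated `degree + 1` times) via `splines::splineDesign`. Points
  outside the boundary are evaluated by continuing the terminal span's
  polynomial — a degree-`degree` Taylor expansion at the boundary, exact
  for piecewise polynomials. This matters when a prediction grid touches
  the observed min/max exactly and keeps out-of-range behaviour
  deterministic and documented. Natural cubic bases (`splines::ns`) are
  linear beyond the boundary by construction.
* **IRLS** starts at $\mu^{(0)} = y + 0.5$ (safe with many zero-count
  days), solves each weighted step by QR decomposition of the weighted
  design rather than normal equations (the seasonal spline block is long
  and nearly collinear), and stops when the relative deviance change is
  $\le 10^{-10}$ or at 100 iterations, flagging non-convergence rather
  than erroring. Rank-deficient designs raise an error naming the
  offending columns.
* **Centering**: the minimum-risk value is found in two passes — predict
  the overall cumulative curve with a provisional center at the exposure
  median, then return the argmin over a 100-point uniform grid. The
  argmin is invariant to the provisional center (it shifts the curve by
  a constant); a flat curve (range $< 10^{-12}$) returns the median with
  a warning.
* **Mode statistic**: computed at each factor's recording precision
  (0.1 degC makes a temperature mode meaningful); ties break to the
  smallest value.
* **Incomplete lag histories** (the first `maxlag` days) are dropped
  from the likelihood, not imputed.
* Dates must be consecutive calendar days; gaps are an error because the
  lag structure assumes contiguity.

## The synthetic-data generator

The generator emulates the structure of an 11-year single-city daily
surveillance series: nine weather factors, each an annual cosine plus
AR(1) Gaussian noise, clipped to physical bounds and rounded to
recording precision; and counts with log-scale seasonality, optional
trend, day-of-week effects, a baseline rate of 863/4078 ≈ 0.21 cases/day,
and overdispersion via NB2 parameterised so that $Var = \phi\,\mu$
(size $= \mu/(\phi-1)$ — quasi-Poisson fixes only the variance function,
so a concrete generating family had to be chosen).

Factor presets were calibrated once, analytically splitting each target
variance into a seasonal share $a^2/2$ and an AR(1) share
$\sigma^2/(1-\rho^2)$ with climatologically chosen seasonal fractions and
autocorrelations, then adjusting bounded factors for clipping-induced
mean shift. A study-length simulation reproduces each factor's long-run
mean within 0.1 SD and its SD within 0.2 SD (tolerances stored per
preset in `calibration_targets()`); the bounded factors reproduce the
characteristic boundary modes (cloud cover at 100%, sunshine at 0 h).

The true surface is $f(x, l) = \gamma\,((x - x_{ref})/s)^2\,e^{-l/\tau}$
— zero at $x_{ref}$ for every lag, so $x_{ref}$ is the minimum-risk
value — smooth enough to be representable by the 3 × 5 basis, which is
what makes parameter recovery a meaningful test of the estimation
machinery rather than of basis approximation.

What the generator deliberately does *not* emulate: cross-factor
dependence (factors are simulated independently, while real humidity,
cloud, sunshine and radiation are strongly coupled), weather physics,
epidemic clustering, or reporting artefacts. Passing tests therefore
validate the statistical machinery on data satisfying the model's
assumptions; they cannot certify behaviour under confounding between
correlated exposures.

## Validation design

The package's correctness argument has three layers, all run by the test
suite and `scripts/acceptance.R`:

1. **Oracle equivalence.** B-spline evaluation is checked against a
   naive Cox–de Boor recursion; the cross-basis against an explicit
   four-level loop; IRLS against a directly coded Newton optimizer and
   `stats::glm`; delta-method variances against explicit-loop quadratic
   forms. Exact identities (partition of unity, RR = 1 with zero-width
   CI at the center, cumulative = sum of lag-specific) are asserted at
   machine precision.
2. **Distributional behaviour.** Pearson dispersion lands near 1 on
   Poisson data and near 2 on NB2 data with $Var = 2\mu$ (4,000-day
   series); 95% CIs for the overall cumulative log RR cover the truth
   92–96% of the time over 100 replicated 5-year studies at the study's
   event rate, and exclude 1 at the empirical P10 in ≤ 10% of null
   replicates. The replicate studies use 1,826 days each — long enough
   to keep the events-per-parameter ratio of the full-length study.
3. **Parameter recovery.** Recovery experiments use a *high-information
   scenario*: 4,000 days at 8 events/day (the scale of the urban
   mortality series on which this model family is classically deployed)
   with $\gamma = 0.3$, giving a well-curved truth. There the fitted
   minimum-risk value lands within one grid step of the true 27 degC and
   the overall cumulative curve's mean absolute error is below twice its
   mean standard error across the interior 80% of the exposure range.
   Estimates are compared to truth centered at the true reference, so
   the curve comparison is not confounded by noise in the center
   estimate; center recovery is assessed separately. At the motivating
   study's own scale (0.21 events/day) the same quantities are reported
   but the minimum is, demonstrably, only weakly identified — a finding
   the README's worked example shows rather than hides.

## Known limitations

* Wald intervals on the log scale with no small-sample correction; with
  ~0.2 events/day and a centering value itself estimated from the same
  fit, null exclusion rates can run slightly above nominal (the
  acceptance script reports the measured rate).
* Significance flags mirror "95% CI excludes 1" with no multiplicity
  adjustment across 9 factors × 15 lags × 12 exposure rows; scanning the
  tables for stars will find some in pure noise.
* One location, one realisation: no meta-analytic pooling, and the
  "minimum-risk" centering degenerates to the fitted curve's argmin (the
  shrinkage machinery of multi-city designs has nothing to shrink
  toward with a single series).
* No attributable-fraction computation, penalized/cyclic splines, or
  autocorrelation-robust covariance.
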