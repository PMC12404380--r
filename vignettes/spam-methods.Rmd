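---
title: "Spurious prospective associations in two-wave panel data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spurious prospective associations in two-wave panel data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prospam)
```

## The problem

Two constructs X and Y are each measured at two occasions, giving variables
`X1, X2, Y1, Y2` and six pairwise correlations. A common analysis regresses
`Y2` on `X1` adjusting for `Y1` and reads a non-zero standardized
coefficient as a prospective (often causal) effect of X on Y. Because
adjusted coefficients are pure functions of correlations, and because
residual terms regress to the mean regardless of the direction of time, the
same data pattern can arise from a stable general association plus
occasion-specific state influence, with no effect of either construct on
the other. This package implements the calculus needed to diagnose that
situation and the generative model that formalizes it.

## Closed-form expected effects

For standardized variables, the expected adjusted effect of a predictor $x$
on an outcome $y$ given one covariate $z$ is

$$\beta_{x,y.z} = \frac{r_{xy} - r_{xz}\,r_{yz}}{1 - r_{xz}^2},$$

which `partial_beta()` implements and `lagged_effects()` applies twice per
direction: forward (`X1` on `Y2` adjusting `Y1`) and time-reversed (`X1` on
`Y1` adjusting `Y2`). Difference-score effects use

$$\beta_{x_1,\,y_2-y_1} = \frac{r_{x_1y_2} - r_{x_1y_1}}{\sqrt{2\,(1-r_{y_1y_2})}},
\qquad
\beta_{\Delta x,\,\Delta y} = \frac{r_{x_1y_1} + r_{x_2y_2} - r_{x_1y_2} - r_{x_2y_1}}
{\sqrt{4\,(1-r_{x_1x_2})(1-r_{y_1y_2})}}.$$

The denominators are standard deviations of difference scores of
standardized components, hence the square roots: the rendered source
formulas show the variances `2(1 - r)` and `4(1 - r)(1 - r)` without a
visible radical, but only the square-root reading yields standardized
coefficients, and only it reproduces the magnitudes of the published pooled
effect rows. `empirical_effects()` is the least-squares counterpart (z-score,
difference, regress, re-standardize); on data carrying a correlation set
exactly, the two routes agree to machine precision — a central identity the
test suite exercises over random structures.

The four effects per direction feed `classify_signs()`. A true increasing
effect predicts signs `(+, -, +, +)` for (forward lagged, reverse lagged,
change, change-on-change); a spurious association predicts both lagged
effects with the same sign, a zero-or-opposite change effect, and a
change-on-change effect opposing the change effect. The zero band defaults
to `epsilon = 0.02` on the standardized scale — a value well below
conventionally interpretable effects; no threshold is prescribed by the
source analyses, so it is exposed as a parameter, and a CI-contains-zero
mode is used when standard errors are available (as in
`analyze_two_wave()`).

## The SPAM

The spurious prospective associations model generates the data as: an
overarching trait loads on the general level of each construct (loadings
`a1 = a`, `a2 = s·a`, equal in magnitude, with `s = -1` for negatively
associated pairs); the general levels load on their occasion measurements
with stabilities `b` and `c`; and an occasion-specific state factor adds
covariance `d` between same-occasion measurements. With all observed
variances fixed at 1 the implied correlations are

* `r_x1x2 = b²`, `r_y1y2 = c²`,
* cross-lagged: `s·a²·b·c` (both lags equal),
* concurrent: `s·a²·b·c + d` (both occasions equal).

`d` is parameterized additively on the standardized-correlation scale (not
as a residual correlation rescaled by residual standard deviations); this
matches the arithmetic of the published parameter tables, where the fitted
`d` equals the concurrent-minus-cross-lagged gap.

### Maximum-likelihood fitting

`fit_spam()` minimizes the normal-theory discrepancy
$F = \log|\Sigma| - \log|S| + \mathrm{tr}(S\Sigma^{-1}) - 4$ over
`(a, b, c, d)`, treating the correlation matrix as a covariance matrix with
unit variances — which is exactly what fitting the SEM to standardized
simulated data does. Ten non-redundant moments minus four free parameters
give 6 degrees of freedom; `chi2 = (n-1)·F` (at n = 10,000 the difference
from `n·F` is below printed precision). The independence model
(`Sigma = I`, `F = -log|S|`, 6 df) is the baseline for CFI and TLI; TLI is
reported raw and capped into [0, 1]; RMSEA is the usual
`sqrt(max(chi2 - df, 0)/(df (n-1)))`.

Numerical choices: optimization is bounded (`a, b, c` inside
`(1e-6, 1 - 1e-6)`, `d` inside `(-1, 1)` with infeasible — non-positive-
definite — steps penalized), starts from the closed-form method-of-moments
initializer `moment_start_values()` (b and c from the autocorrelation
square roots, a from the rescaled mean |cross-lagged| correlation, d from
the concurrent-minus-cross gap), adds a coarse multi-start over `a` and `d`
because adversarial structures far from the model family can hold local
basins, and declares convergence only when a restart from the solution
cannot improve F by more than 1e-10. Self-fits (fitting the model to its
own implied matrix) recover parameters to 1e-5 with chi-square below 1e-6
across the tested parameter grid.

### A reproducibility caveat on chi-square

The chi-square of this model depends *only* on how far the two concurrent
correlations are from their common implied value and the two cross-lagged
correlations from theirs (plus their interaction); the parameter estimates,
by contrast, depend essentially on pair means and autocorrelations. Those
pair contrasts in published pooled tables are of order 0.01–0.06 — the same
order as the rounding error of a table printed to two or three decimals.
Parameter estimates computed from printed tables are therefore stable to
the last printed digit, while chi-square (and anything derived from it:
CFI, TLI, RMSEA) can shift by tens of percent depending on sub-rounding
detail of the input correlations. Users comparing `fit_spam()` output
against published chi-squares should expect agreement in parameters and in
qualitative fit, not in the chi-square's printed digits, unless they supply
the unrounded input matrix.

## Simulation

`simulate_two_wave()` (and `simulate_spam()` for model-implied targets)
draws multivariate-normal data. In exact mode the draw is whitened and
recolored by the Cholesky factor of the target (via
`MASS::mvrnorm(empirical = TRUE)`), so the *sample* correlation matrix
equals the target to machine precision for any `n > 4`; this makes the
simulate-then-fit pipeline deterministic given its inputs, which is how
published parameter tables reproducible to three decimals must have been
computed. Stochastic mode is an ordinary seeded draw for studying sampling
variability. Non-positive-definite targets are refused, never smoothed.

## Meta-analysis

`meta_pool()` pools Fisher-z transformed per-study values under a
random-effects model: tau² by REML (default; the standard tooling default)
or DerSimonian–Laird (closed form, kept for hand-checkable verification),
inverse-variance weights `1/(v + tau²)`, normal-theory CIs, Cochran's Q on
fixed-effect weights. The sampling variance of a transformed correlation is
`1/(n-3)`; the same variance is deliberately used for transformed
standardized regression effects — the convention of treating standardized
betas like correlations. That is an approximation (no exact closed form
exists for these betas' sampling variance), and it is the package's choice
where the source analyses leave the formula unstated.

The I² point estimate uses the Q-based Higgins formula
`max(0, (Q - df)/Q)·100`; its confidence interval comes from the Q-profile
interval for tau² (via metafor), whose I² definition is tau²-based. The two
definitions coincide under DL but differ slightly under REML; the point
estimate keeps the Q-based form for comparability with published tables.

`meta_table()` runs the full 14-analysis layout of a two-wave synthesis:
six pooled correlations plus four effects per direction, with per-row study
counts reflecting availability (studies lacking time-2 outcome measures
drop from rows that need them), and with the change-on-change rows
identical across directions by construction.

`make_study_fixtures()` generates synthetic per-study tables around a SPAM
population: Fisher-z perturbation with between-study SD `tau_z`, eigenvalue
clipping and re-normalization to repair infeasible perturbed matrices
(fixture generation only — user data are never repaired), then a stochastic
draw per study. Defaults (`k = 10` studies, n of a few hundred,
`tau_z = 0.1`) mirror the scale of the published loneliness/social-anxiety
synthesis (ten studies, total N just under 4,000, substantial
heterogeneity). The generator emulates extraction tables — independent
studies with known population structure and missing-at-design entries — and
does not emulate correlated sampling error within studies, publication
bias, or moderators; tests passing on these fixtures show the pooling
machinery is correct, not that any real synthesis is unbiased.

## The evaluation pipeline

`spam_evaluation()` chains the six-step procedure: simulate a large dataset
at the input correlations, fit the SPAM, simulate a new dataset at the
SPAM-predicted correlations, compute all effects in it empirically, compare
the lagged effects with the input-implied ones, and classify sign patterns.
Defaults: `n = 10000`, exact mode (deterministic reports; stochastic mode
is retained behind a flag), seed required. `analyze_two_wave()` applies the
same logic directly to raw data, with least-squares standard errors
providing the CI-based zero band.

Problem sizes in the test suite follow the study conditions: evaluation
runs at n = 10,000; the oracle-equivalence property uses 50 random
correlation structures at n = 200 (the identity is exact, so size is
immaterial); self-fit recovery covers the full 162-point parameter grid;
meta recovery uses k = 30 studies and a dozen replicates, which is enough
to pin the REML tau² to well within the 50% band asserted.

## Known limitations

* Two constructs, two occasions, equal loadings across occasions; no
  extension to three-plus waves (where random-intercept cross-lagged
  designs live).
* No standard errors for SPAM parameters, and point RMSEA only (no
  profiled CI).
* Normal data generation only; listwise-complete raw data expected.
* The chi-square sensitivity described above: global-fit statistics from
  rounded published inputs are not reproducible at printed precision, while
  parameter rows are.
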