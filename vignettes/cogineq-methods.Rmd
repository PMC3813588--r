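---
title: "Methods: measuring and decomposing inequality in children's cognitive function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and decomposing inequality in children's cognitive function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogineq)
```

This vignette is the package's own account of the statistical machinery: the
estimands, the assumptions behind each stage, the tunable parameters and
their defaults, the numerical decisions, and what the synthetic-data tests do
and do not establish about real survey data.

## The estimand

The outcome is a child's score on a 12-item cognitive test (0–12), observed
together with household per-capita expenditure (PCE), a person sampling
weight, and a set of child, parental and household covariates, in two
repeated cross-sectional rounds. The quantity of interest is the **relative
concentration index (RCI)** of the age-standardized score over the
expenditure ranking,

$$C \;=\; \frac{2}{\mu} \sum_i w_i\, y_i \,(R_i - \tfrac12),$$

with normalized weights $\sum_i w_i = 1$, weighted mean $\mu = \sum_i w_i
y_i$, and $R_i$ the weighted fractional rank of child $i$ in the PCE
distribution ($R_i$ is the midpoint of the child's cumulative-weight
interval; its weighted mean is exactly $\tfrac12$ on every input — the
package tests this identity rather than assuming it). $C > 0$ means higher
scores are concentrated among children from better-off households.

Because the z-scored outcome takes both signs, the index is not confined to
$[-1, 1]$ and is undefined at $\mu = 0$; no bounded-outcome rescaling
(Erreygers- or Wagstaff-style) is applied, keeping the estimand the plain
relative index. `rci()` errors at $\mu = 0$ exactly and warns when $|\mu| <
10^{-6}$.

## Age-specific standardization via Hozo summaries

Raw item-count scores are left-skewed (mass near the ceiling) and rise with
age. Rather than using per-cell sample moments, the per-(round, age) mean
and SD are recovered from each cell's minimum $a$, median $m$, maximum $b$
and size $n$ with Hozo, Djulbegovic and Hozo's estimators:

* mean: $(a + 2m + b)/4$ for $n \le$ `mean_cutoff`, the median beyond it
  (published recommendation: cutoff 25);
* SD: the small-sample variance formula for $n \le 15$, range/4 for
  $15 < n \le 70$, range/6 beyond.

The summaries are computed **unweighted** — they are order statistics, and no
weighted variant is defined here — and cells are integer ages within round,
since ages are reported in whole years (7–14). Both branch thresholds are
arguments of `hozo_mean()`, `hozo_sd()` and `fit_zscore_model()`.

**Which branch the pipeline uses.** With cells of several hundred children
the published recommendation reduces the Hozo mean to the cell median. Under
left skew the median exceeds the mean in essentially every cell, so
median-centering forces the mean z-score *negative* and pushes $\mu$ toward
zero — and the relative index, which divides by $\mu$, becomes unstable and
sign-flipped relative to the underlying covariance. Applying the quartic
$(a+2m+b)/4$ formula at every $n$ keeps the centering below the cell mean
(the minimum drags it down), yielding a positive mean z and a stable index —
the behaviour reported for this outcome (complete-case mean z of roughly
+0.2 to +0.3 and a positive, declining RCI). `run_pipeline()` therefore
defaults `hozo_mean_cutoff = Inf`, while the low-level functions keep the
published cutoffs as defaults. Analysts who prefer strict adherence to the
published branching set `hozo_mean_cutoff = 25` in `pipeline_config()`.

Degenerate cells (zero estimated SD, e.g. all scores identical) abort with
the cell named rather than silently producing infinite z-scores.

## Delta-method inference and its calibration

The SE of the index uses the Kakwani–Wagstaff–van Doorslaer delta-method
estimator, in the weight-substituted ("conindex"-style) convention: with
rows sorted by rank and $q_i$ the cumulative weighted outcome share,

$$\widehat{\mathrm{var}}(C) = \frac{1}{n}\Big[\sum_i w_i a_i^2 - (1+C)^2\Big],
\qquad a_i = \frac{y_i}{\mu}(2R_i - 1 - C) + 2 - q_{i-1} - q_i.$$

Confidence intervals are normal-approximation ($\pm 1.96\,$SE at 95%). A
numerically negative variance (possible at exactly zero inequality) is
clipped to zero with a warning. The estimator is validated by simulation:
under a null with no rank gradient, 95% intervals cover zero in 95% ± 2% of
1000 replicates at $n = 500$, and matched simulations confirm the
$1/\sqrt{n}$ scaling. A nonparametric bootstrap (`rci_se_bootstrap()`,
re-ranking within each resample) is provided as a cross-check, not as the
default. Ranks and weights are treated as fixed; the survey's multi-stage
design beyond the person weights is out of scope.

## Wagstaff decomposition

A weighted linear model $y_i = \alpha + \sum_k \beta_k x_{ik} +
\varepsilon_i$ (intercept always included; independence working model with
weights only) induces the exact identity

$$C = \sum_k \eta_k C_k + \frac{GC_\varepsilon}{\mu}, \qquad
\eta_k = \frac{\beta_k \bar x_k}{\mu},$$

because the weighted mean rank is exactly $\tfrac12$ (so the intercept drops
out) and the residuals carry the remainder. The package computes each
contribution as $\beta_k \cdot GC_k / \mu$ — algebraically $\eta_k C_k$ but
defined even when $\bar x_k = 0$ — and asserts additivity to $10^{-10}$ in
its own pipeline audit and tests. Parental education enters as high-school
and university attendance dummies with none/primary as the reference, the
coding that matches the published contribution tables. The decomposition is
**complete-case**: rows missing any model variable are dropped with a logged
count, and weights are renormalized on the retained rows. Shares are signed
percentages; negative shares are meaningful (a contributor concentrated
among the poor but raising scores offsets pro-rich inequality).

## Oaxaca-type change decomposition

For rounds $t-1, t$ the change splits per contributor into a
changing-inequality and a changing-elasticity term. Two-period
decompositions of this form are not unique; the package defaults to

$$\Delta C_k = \eta_{kt}\,(C_{kt} - C_{k,t-1}) + C_{k,t-1}\,(\eta_{kt} - \eta_{k,t-1}),$$

(current-period elasticity on the inequality change, base-period inequality
on the elasticity change), with the mirrored and the symmetric
average-weight variants available via `weighting =`. All three satisfy the
additivity identity with the residual-term difference; only the split
between the two columns changes. Percents are computed from unrounded terms
against the total change including the residual, so a contributor moving the
index in the direction of the overall change gets a positive percent even
when both are negative. Report tables round to two decimals and integer
percents, and never recompute percents from rounded terms — on published
tables of this kind the rounded columns can miss the rounded total by a few
hundredths, which is expected rounding drift, not an identity failure.

## Gibbs-sampled uncertainty for contribution shares

Uncertainty in the shares is propagated from the regression coefficients by
a conjugate normal–inverse-gamma Gibbs sampler on the weighted likelihood
$\prod_i N(y_i;\, x_i'\beta,\ \sigma^2 / w_i)$ with weights scaled to mean
one. Defaults are vague — $\beta \sim N(0, 10^6 I)$, $\sigma^2 \sim
\mathrm{InvGamma}(10^{-3}, 10^{-3})$, 5000 retained draws after 1000 burn-in
— and everything is configurable in `mcmc_config()`. The chain initializes
at the weighted least-squares solution; with conjugate full conditionals it
mixes essentially immediately, and no convergence machinery beyond trace
export (`write_posterior_draws()`) is provided.

Per draw, contributions are recomputed with $C_k$, $\bar x_k$, $\mu$ and the
ranks held at their sample values; only $\beta$ (and $\sigma^2$) vary. The
95% interval is the equal-tail (2.5th, 97.5th) percentile pair of the share
draws, using linear-interpolation order statistics. Holding the ranks fixed
understates rank uncertainty; this is a deliberate, documented
simplification — the published analysis gives no indication of resampling
ranks either.

## Missing data

Multiple imputation is used **only** for index estimation, never for the
decomposition (no established rule pools decomposition shares). The sampler
is a transparent chained-equations ("regression switching") implementation:
within each round, each incomplete column is regressed on all other model
columns over its observed rows; continuous columns are imputed by a proper
draw (residual variance from its scaled inverse-$\chi^2$ posterior,
coefficients from their normal posterior, plus Gaussian noise), binary and
ordered categorical columns by thresholding the same latent draw to the
nearest level. Initial gaps are filled from each column's observed empirical
distribution; defaults are 20 imputed datasets and 50 sweeps; the outcome is
a predictor in every imputation model while the sampling weight is not.
Predictive-mean-matching parity with survey-software MICE implementations is
deliberately not attempted.

Pooling follows Rubin's rules with Barnard–Rubin small-sample degrees of
freedom. One structural consequence of the package's missingness design:
the outcome, the ranking variable and the weight are never masked (the MAR
mechanism must condition on always-observed fields), so all completed
datasets yield the *same* index and the between-imputation variance is
exactly zero; the pooled interval then reduces to the within-imputation
normal interval. The value of MI here is row restoration: complete-case
analysis drops incomplete rows — disproportionately poor ones under
expenditure-dependent MAR — which truncates the poor tail and depresses the
index, while the imputed analysis retains all rows. The package reproduces
this contrast (MI index > complete-case index) as a property test.

## The synthetic-data generator

`generate_survey()` emulates the structure the analysis assumes, with
defaults set to the published round conditions: sample sizes 6179 / 6680,
log-PCE moments $N(11.93, 0.70^2)$ and $N(12.82, 0.65^2)$, covariate
prevalences matched to the published complete-case summary table, and
outcome-model coefficients patterned on the published per-round regression
columns. Specifically:

* **Expenditure and ranks.** Log PCE is normal; every covariate model is
  monotone in the expenditure rank with a configurable gradient (log-odds
  scale for binary and ordered-education models, log-mean scale for the
  gamma-distributed parental CES-D scores). Intercepts are calibrated
  numerically so marginal prevalences match their targets regardless of the
  gradients.
* **Scores.** A latent index — contributor effects (z-score units, scaled by
  `score_scale` = 2.5 raw points per z-unit), an age trend (0.7 points/year),
  Gaussian noise (0.75 z-units) — is rounded and censored into 0–12 with the
  center high enough (8.5 at mid-age) that ceiling censoring produces the
  left-skew-increasing-with-age pattern of real item-count tests.
  `true_betas` are declared in z-units per the outcome-model convention;
  exact-recovery tests compare fitted raw-score coefficients divided by
  `score_scale` against them, because the downstream z-transform divides by
  the *Hozo-estimated* cell SD, which is not the latent scale.
* **Weights** are gamma with mean 1 and configurable SD (0 recovers the
  unweighted case). **Missingness** is MAR given log PCE and age only, with
  the marginal per-cell rate calibrated exactly and the default gradient
  concentrating gaps among poorer households; the outcome, age, expenditure
  and weight are never masked. The default per-cell rate (0.04–0.045 over
  ten eligible columns) reproduces the roughly one-third incomplete-row
  fractions of the real rounds.

What the generator does **not** emulate: multi-stage cluster sampling,
household-level correlation between siblings, panel attrition between
rounds, item-level psychometrics, or informative weighting. Passing tests
therefore establish the correctness of the estimators and identities under
a clean superpopulation model, not robustness to design effects; on real
IFLS-like data the delta-method SE will understate design-based uncertainty
to the extent of clustering.

The raw-score distribution by age is not published, so the generator's
skewness geometry (`score_center`, `score_scale`, `age_slope`) is a modeling
choice, fixed once at values that give realistic ceilings, not a calibrated
target.

## Numerical choices

* **Ties in the ranking variable** get their own cumulative-weight rank in
  stable input order by default; `ties = "average"` assigns tie groups their
  weighted mean rank. Both preserve the exact mean-rank-$\tfrac12$ identity.
* **Rank-deficient designs** abort with the collinear columns named, at the
  regression stage for analysis models; inside the imputation sweeps,
  collinear predictors are dropped by QR pivoting instead, since
  interim imputation models need to be fault-tolerant.
* **Degenerate inputs**: zero-mean outcome → error; zero-spread z-cell →
  error naming the cell; numerically negative delta variance → clipped with
  a warning; zero total index → shares `NA` with raw contributions still
  returned.
* **Determinism**: every stochastic stage draws from a private seeded RNG
  stream (never disturbing the caller's RNG state); identical configurations
  are byte-identical on rerun, which the pipeline tests assert at the
  artifact level.

## Problem sizes used in the test suite

The suite exercises: exact identities on 200 random tables of $n = 200$;
delta-method coverage on 1000 replicates at $n = 500$; the closed-form
$C = 1/3$ limit at $n = 10^5$; coefficient recovery (least squares and
Gibbs, 1200 retained draws) at $n = 20{,}000$ with the low-censoring
generator settings; and multiple-imputation recovery at $n = 4000$ with a
30% per-cell MAR rate, $m = 20$ and 10 sweeps. These sizes give
Monte-Carlo error comfortably inside each test's tolerance while keeping
the default run fast.

## Known limitations

* The relative index with a sign-switching outcome is unbounded and
  mean-sensitive; the package surfaces rather than corrects this (see the
  standardization section).
* Delta-method and Gibbs inference both condition on the estimated ranks
  and, for shares, on the plug-in $C_k$, $\mu$; neither propagates ranking
  uncertainty.
* The chained imputation sampler is intentionally minimal; it is congenial
  with the analysis model by construction in the synthetic setting but has
  no predictive-mean-matching safeguards for real, irregular data.
* Two-round change decomposition only; longer trends require repeating the
  pairwise analysis.
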