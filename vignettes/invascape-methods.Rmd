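---
title: "Methods: models, parameters, and design choices in invascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in invascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invascape)
```

`invascape` analyses a plant invasion at the scale of a trade port: how
widespread and dominant the invader is in plot surveys, how risky it is
under a multi-criteria scoring scheme, what drives its plot-level
dominance, and where it could grow under current and future climates.
This vignette documents the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Survey statistics

A survey is a long table, one row per plot × species, with abundance
(individuals), height (cm) and cover (fraction of the 1 m² plot). Within
a plot, each metric is normalized by its plot total, and a species'
importance value is

$$IV = \tfrac{1}{3}(rel\_height + rel\_cover + rel\_abundance).$$

The equal-weight three-term mean is the standard convention for
herbaceous quadrats where frequency across subplots is not recorded; the
weights are an argument of `relative_metrics()` for schemes that include
relative frequency. Plot diversity is the Shannon–Wiener index over
abundance shares, in nats (`base` switches to bits); abundance shares
rather than cover shares are the default because counts are the most
consistently recorded metric, and `shannon_index()` errors on plots with
no positive abundance rather than silently returning 0. A plot whose
height (or cover) column is all zeros gets zero relative values plus a
warning — a degraded row should not kill a 595-plot batch.

Community types are keyed by each plot's dominant species (highest IV;
lexicographic tie-break so reruns are stable). Group comparisons use the
Welch unequal-variance t test — the safer default when one species (a
tall clonal invader) has a very different spread from the rest — with
significance tiers `*`, `**`, `***` at 0.05, 0.01, 0.001.

## Risk scoring

The scoring engine aggregates 14 expert-assigned indicators, each on a
closed [0, 4] scale, into four components and a composite (see the
README for the formulas). Two conventions required a decision:

* **Scale.** Indicators live on [0, 4] so the composite spans the
  full classification range 0–4.0; the scale is stored per
  scoresheet, so other frameworks can reuse the engine.
* **Boundaries.** The conventional level ranges share their endpoints (1.2
  and 2.8 belong to two ranges as printed). Ties go to the *higher-risk*
  level: a composite of exactly 2.8 is level 1. This is the
  precautionary reading and makes `classify_level()` a total monotone
  step function.

The composite uses unrounded components; rounding to two decimals is
display-only. The geometric-mean structure means any zero component
(e.g. zero spread scores) zeroes the composite, and the composite is
always sandwiched between the smallest and largest component — both are
enforced as tests.

## Driver model

`build_driver_table()` assembles one row per plot: the response is the
invader's importance value (0 where absent — absence is informative for
invasibility, so those rows are kept), and the predictors are the plot's
Shannon index plus bioclim layers sampled at the plot's grid cell. Rows
on nodata cells are dropped and counted. Predictors are z-scored
(population SD) before fitting so coefficient magnitudes are comparable
effect sizes. The family is Gaussian with identity link: the conventional
summary statistic for this model class is a plain R², and the bounded
response stays well inside (0, 1) in practice; a quasi-binomial logit
alternative is available via `family = "quasibinomial"` for responses
piling up at the bounds. Collinearity is screened by greedy removal of
pairwise |Spearman ρ| > 0.75, keeping the member more correlated with
the response.

## Maximum-entropy SDM

The model is the classical presence–background Gibbs distribution over
landscape cells,

$$q_\lambda(i) = \frac{e^{\eta_i}}{\sum_{b \in B} e^{\eta_b}}, \qquad
  \eta_i = \sum_j \lambda_j f_j(i),$$

with features $f_j$ min–max scaled to [0, 1] over the background sample
$B$: linear and quadratic transforms of each continuous layer, forward
and reverse hinges at background quantile knots (5 per layer by
default), indicator features for categorical land cover, and optional
pairwise products (off by default — at small presence counts they mostly
add variance). The fitted weights minimize the convex objective

$$L(\lambda) = -\overline{\eta}_{pres} + \log\textstyle\sum_B e^{\eta}
  + \sum_j \beta_j |\lambda_j|,$$

by cyclic coordinate descent: a one-dimensional Newton step with
soft-thresholding per feature, backtracked until the full objective
decreases, so the objective is non-increasing across every accepted
update (a tested invariant, as is $\sum_B q_\lambda = 1$ after every
fit). Convergence is declared when a full cycle improves the objective
by less than `tol = 1e-7`; failing to converge within `max_cycles`
(default 2000) is an error carrying the remaining gap, not a silent
return. Per-feature penalties $\beta_j$ scale with the feature's
background SD and shrink with the square root of the presence count
(hinge features get a 0.5 class multiplier, following common maxent
practice); the single user-facing knob is `reg_multiplier`.

The default output is the cloglog transform
$1 - \exp(-e^{H} \cdot raw)$, with $H$ the entropy of the background
distribution — the modern maxent default, interpretable as an occupancy
probability under a constant-area assumption; `logistic` and `raw` are
available by flag. Predictions on new data clamp features outside the
training-background range to its bounds (the standard maxent treatment:
responses plateau rather than extrapolate under novel climates;
`clamp = FALSE` disables it). Duplicate presences in one grid cell are
collapsed by default (`dedupe`); spatial thinning beyond that is out of
scope.

Diagnostics follow the conventions of the maxent ecosystem: *percent
contribution* credits each accepted coordinate update's objective gain
to the variable owning the feature; *permutation importance* permutes
one variable across the pooled evaluation points and normalizes the AUC
drops; *jackknife gains* refit with only/without each variable and
report regularized training gain ($\log n_B$ minus the optimized
objective); *response curves* sweep one variable over its background
range with the others held at their background mean (categorical at the
mode). `tune_model()` grid-searches regularization multipliers and
feature-class sets, scored by AICc on the presence likelihood (k =
non-zero weights) by default, or by held-out AUC.

AUC is the rank (Mann–Whitney) statistic of presence vs background
scores with ties counted ½ — a presence–background AUC, so its ceiling
is below 1 when presences occupy background cells.

## Suitability classes and scenario accounting

`jenks_breaks()` is an exact Fisher–Jenks dynamic program: it minimizes
the within-class sum of squared deviations over contiguous partitions of
the sorted values — verified against exhaustive enumeration for small
inputs. Surfaces larger than `max_n = 10000` values are classified on a
seeded subsample with the exact DP (documented, reproducible, and the
only approximation in the module). Breaks are reported as midpoints
between adjacent class boundary values; classification intervals are
left-closed/right-open with the top class closed, and nodata propagates.

Per-class area is cell count × cell area; the total-suitable share pools
everything above the "non" class, and the valid-area denominator
excludes nodata. For scenario comparison the default is to **reuse the
current-scenario breaks** for future surfaces, so area deltas reflect
suitability change rather than re-binning; per-scenario re-binning is
available via `rebin_scenarios = TRUE` (which of the two an existing GIS
workflow used is often undocumented — both are provided, the default is
the one that makes deltas interpretable).

## Synthetic data: what it emulates, and what not

The generators provide every input with known ground truth:

* `gen_landscape()` — each layer is seeded white noise smoothed by a
  truncated moving-average kernel (half-width `smoothness` cells;
  summed-area implementation, no spatial dependencies) and min–max
  rescaled to plausible subtropical-monsoon ranges (annual mean ≈ 17 °C,
  annual precipitation ≈ 1500 mm; temperatures °C, precipitation mm).
  Cross-correlations are planted by mixing latent fields
  ($latent_j \leftarrow \rho\, latent_i + \sqrt{1-\rho^2}\, latent_j$)
  before the monotone rescale, so Spearman targets survive; the default
  plan correlates precipitation totals (bio12/bio13/bio16) and summer
  temperatures (bio5/bio10) while leaving the driver variables
  unplanned, below the 0.75 screening threshold. Land cover is a
  quantile quantization of its own latent field.
* `gen_occurrences()` — cells sampled with probability ∝ exp(η) under a
  `truth_model()` whose coefficients apply to min–max-normalized layers:
  exactly the likelihood `fit_maxent()` maximizes, which is what makes
  parameter recovery a meaningful oracle.
* `gen_survey()` — companion communities with geometric-series
  abundances (richness 3–10), and an invader importance target
  $clip(\beta_0 + \beta_{sh} H + \beta_{bio6} z_{bio6} + \varepsilon,\,0,\,0.95)$
  realized through the invader's height/cover/abundance shares. The
  invader enters with a small abundance (1–3 ramets, enlarged only when
  a high target requires it), so its dominance does not mechanically
  depress the measured Shannon index — otherwise target noise leaks into
  the predictor and inflates R² regardless of $\sigma$. Defaults
  $\beta_{sh} = -0.4$, $\beta_{bio6} = +0.05$ (colder plots less
  invaded), `absence_below = 0.32` and $\sigma = 0.11$ were calibrated
  once so that, at 595 plots, the invader occurs in about two thirds of
  plots and the driver GLM's R² sits near 0.45 — the regime the
  analysis is designed for — and then frozen.
* `gen_risk_scoresheet()` — bounded, seeded rejection sampling of
  integer indicators until the assessment yields the requested level.

What the generators do **not** emulate: coastline/port geometry,
anisotropy, temporal climate trajectories (future stacks are independent
perturbations via `gen_scenario_stack()`), observation error in species
identification, and spatial sampling bias in occurrences. Passing tests
therefore demonstrate correctness of the estimators on well-specified
synthetic data, not robustness to the biases of real survey data.

## Numerical choices and problem sizes

All randomness flows through explicit seeds (`with_seed()` restores the
caller's RNG state, so package calls never perturb a user's stream).
Ties: lexicographic for dominant species, ½ for AUC ranks, higher-risk
for level boundaries, left-closed for class intervals. Degenerate
inputs: constant layers are excluded from screening with a warning;
constant-over-background features are dropped before fitting; all-zero
plot metrics warn and return zeros; empty datasets error.

The test suite runs at deliberately desk-scale sizes — landscapes of
30×30 to 100×100 cells, 150–2000 presences, backgrounds up to 10,000,
and a 100-seed replication of the 595-plot driver analysis — chosen so
the full suite completes in well under a minute while keeping every
statistical check at the sample sizes its tolerances were derived for.
The Gibbs parameter-recovery fixture uses two iid U-shaped (Beta(0.3,
0.3)) layers rather than a smoothed landscape: on a strongly
autocorrelated, min–max-rescaled field the Fisher information at 2000
presences cannot pin coefficients to 15%, so the fixture is built where
that bound is a comfortable two-sigma statement.

## Known limitations

* The maxent fitter is dense: very large feature sets × backgrounds
  (≫10⁵ cells) would want the usual sparse/compiled tricks.
* No geographic projections: synthetic grids are metric by construction,
  and area accounting assumes equal-area cells.
* The jackknife refits models per variable, so its cost grows linearly
  with the variable count; it is not run inside the default pipeline.
* Percent contribution is path-dependent (it credits the optimizer's
  update order), which is inherent to the definition; permutation
  importance is the path-independent alternative reported alongside.
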