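---
title: "Methods: phenotype distribution models by componentwise boosting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype distribution models by componentwise boosting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmboost)
```

## Scope and data model

`pdmboost` models a quantitative livestock trait — body weight of village
chickens raised under scavenging conditions — as a smooth additive
function of gridded environmental covariates, and projects the fitted
function over a landscape to rank regions per breed. The pipeline runs
from raw biweekly group weighings in georeferenced households to masked
prediction surfaces and precision reports. Because the on-farm data such
analyses use are typically access-restricted, the package ships a
first-class simulator that reproduces the *statistical structure* of the
design: one breed per household, group weighings every two weeks, smooth
spatially correlated covariate fields, rectangular administrative
regions, an arid region whose conditions fall outside the tested range,
and known contamination.

## Cleaning rules

Group weights become average individual weights by exact division. Three
filters follow, each with a strict boundary:

* average weight below 50 g removed (exactly 50 g kept) — implausibly
  small values are data-entry errors;
* households whose maximum reported bird count exceeds 30 are removed
  entirely (30 kept) — more birds than were delivered indicates mixing
  with the farmer's own flock;
* ages below 6 weeks removed (week 6 kept) — chicks were delivered at six
  weeks, earlier records cannot refer to the tested birds.

Dispositions are logged per record, attributed to the first matching rule
in the order above. The kept set is order-invariant because the rules are
independent predicates; only the log attribution depends on the order,
and a test asserts the order-invariance of the kept set.

## The household growth model and LSmeans

Within one breed and age phase, average weight is regressed on age:

$$y_{hw} = \beta_0 + s_h \, w + e_{hw},$$

a common intercept with a household-specific slope. The parameterization
encodes two assumptions: chicks of a breed weigh the same at hatching
(week 0), and households differ in growth *rate*, not in starting weight.
Week is continuous; the design is an arrow matrix (one dense intercept
column, one slope column per household), so the normal equations are
solved exactly by a Schur complement on the intercept rather than a dense
factorization — identical to `lm()` to 10+ digits (a test checks this,
and another checks agreement with `emmeans`), but linear in the number of
households. Each household's LSmean and its standard error are the fit
evaluated at the phase-average week (the mean of the `week` field over
the phase, breeds pooled), which standardizes households measured at
different ages. Designs where slope and intercept are confounded (all
records at one week) raise a classed rank-deficiency error rather than
returning an arbitrary solution; no other rank deficiency can occur in
this design because weeks are positive.

## Componentwise L2 boosting with P-spline base-learners

The LSmeans of each breed-phase dataset are regressed on the
environmental covariates of the household cells by componentwise
functional gradient descent for squared-error loss. One deliberately weak
base-learner per covariate; at iteration $m$ every base-learner is fitted
to the current residuals and only the best (smallest in-bag RSS)
advances the additive predictor by a factor $\nu$. Selection and
shrinkage together perform variable selection and smoothing at once.

Base-learners are penalized B-splines: cubic splines over 20 equal-width
knot segments spanning the covariate's training range (basis dimension
20 + 3), with a second-order difference penalty on adjacent coefficients.
The penalty weight of every base-learner is calibrated by monotone
bisection on $\log\lambda$ so the smoother's effective degrees of
freedom, $\mathrm{tr}\,B(B'B+\lambda D'D)^{-1}B'$, equal 4 within
$10^{-6}$. Equal flexibility is what makes selection comparable across
covariates; without it, wiggly learners would win spuriously.

Numerical choices worth recording:

* The intercept is an offset (the response mean), and each base-learner
  carries a sum-to-zero constraint on its fitted values ($1'Bv = 0$),
  handled by an orthonormal null-space reparameterization. Fitted values
  are invariant to the choice of null-space basis; the test suite's
  independent oracle exploits this by imposing the same constraint
  through a KKT system instead.
* Ties in base-learner selection break to the lowest column index, and
  ties in the stopping iteration to the smallest iteration, so runs are
  exactly reproducible.
* Evaluation outside a covariate's training range extrapolates the spline
  linearly from the boundary value and first derivative. This keeps
  predictions finite near the support; genuinely out-of-range cells are
  the mask's job, not the spline's.
* Knot grids are built with exact endpoints (`seq(..., length.out)`), so
  evaluation exactly at the training maximum never falls foul of
  floating-point knot arithmetic.

Defaults ($\nu = 0.1$, 20 knots, cubic, penalty order 2, df 4, bootstrap
early stopping with $B = 25$ resamples) follow the conventions of
model-based boosting software for Gaussian responses; all are exposed in
the configuration. With a single base-learner and many iterations the
boosted fit converges to the unpenalized basis regression ("twicing");
the test suite asserts this at $m = 5000$ on a 30-point toy with a
4-segment basis, where the smallest smoother eigenvalue is large enough
for 5000 steps to reach the limit numerically.

Early stopping draws $B$ bootstrap resamples of the rows (k-fold
cross-validation is available behind the same interface), reruns the
boosting path on each in-bag set with the full-data bases and penalties,
and picks the iteration minimizing the mean out-of-bag squared error.
Stopping is per model: each breed-phase combination gets its own
$m_{stop}$. Variable importance accumulates the per-iteration in-bag risk
drop to the selected base-learner; importances are non-negative and sum
exactly to $\mathrm{risk}(0) - \mathrm{risk}(m)$, which the suite asserts
for every fit it creates.

## Spatial prediction, masking and suitability

A fitted model predicts cellwise over the covariate stack. A cell is
masked when *any* model covariate lies strictly outside the closed
interval of that covariate's training range — the conservative reading of
excluding areas (deserts) whose conditions the tested birds never
experienced. The mask derives from each model's own training rows since
models are fitted independently. Region suitability is the mean predicted
weight over a region's unmasked cells by default (median and max are
options; the choice of summary is genuinely open and is therefore
config-exposed and recorded in outputs). Precision is the within-region
Pearson correlation between predictions at household covariates and the
household LSmeans, reported with the large-sample standard error
$(1-r^2)/\sqrt{n-1}$ and gated at $n > 25$ households (the standard
sample-size rule for estimating correlations); these are in-sample
correlations, so out-of-sample precision may be lower.

## What the simulator emulates — and what it does not

`sim_env_stack()` builds each covariate layer by convolving white noise
with an isotropic Gaussian kernel (scale `smoothness`, in cells) and
rescaling affinely to a plausible per-variable range (temperatures in
°C, precipitation in mm, elevation in m, cultivated land in %). Kernel
smoothing gives spatial autocorrelation and between-layer independence
without the machinery of a full geostatistical model. Regions are
contiguous rectangular column blocks — a reproducible, trivially
testable stand-in for administrative states; the last is a designated
desert whose first layer is shifted strictly above every other region's
range, so range masking has something to catch *by construction* rather
than by a priori masking. Households are placed uniformly over eligible
(non-desert, non-nodata) cells, and breeds are assigned round-robin after
a seeded shuffle so per-breed counts differ by at most one.

`sim_weight_records()` draws, per household and sex, biweekly group
weights $n_{hw}(\mu_{hw} + \varepsilon)$ with group sizes uniform on
3–25 (roughly 25 delivered chicks with attrition) and Normal weighing
noise on the mean individual weight — the within-household error model is
an assumption of this generator, not an observed property of real
weighings. The true growth line is

$$\mu_{hw} = \beta_0^{*} + s_h w,\qquad
  s_h = \bar s_{breed} + d_h + \frac{\sum_j f_j(x_{hj}) + b_h}{w_{ref}},$$

with $d_h \sim N(0, \sigma_s)$ and $b_h \sim N(0, \sigma_H)$. Routing the
environmental and household effects through the *slope* (rather than a
parallel intercept shift) is a deliberate design choice with two
justifications. Biologically, a common hatch weight with
environment-dependent growth rate matches the assumption the analysis
model itself makes — the environment affects how fast birds grow, not how
big they hatch. Statistically, it places the truth inside the fitted
model family, so with zero weighing noise the LSmeans recover the
generator's ground truth *exactly* (to $10^{-8}$ relative; asserted),
which is what makes parameter-recovery testing sharp. At the reference
week $w_{ref}$ (default 16.5, the middle of the growing phase) the
covariate contribution in grams equals $\sum_j f_j(x_{hj})$ exactly, so
effect sizes are specified on the gram scale.

The default truth uses three active covariates with distinct smooth
shapes — annual mean temperature through a sine arc (0–300 g at
$w_{ref}$), annual precipitation through a quadratic bump (0–250 g),
elevation through a declining logistic (±120 g) — against a household
effect of 80 g, weighing noise of 50 g, and growth rates near
48–62 g/week by breed, chosen so that simulated growing-phase LSmeans
(≈ 900–1500 g with a spread of several hundred grams) resemble published
on-farm ranges. Because smoothed fields concentrate mid-range, realized
per-component standard deviations are roughly a quarter of the nominal
amplitudes.

Contamination injection is exact and disjoint by class: under-50 g
records and under-6-week records are added rows in otherwise clean
households, and over-30-bird households get one inflated count; every
injected record (and every record of an inflated household) is flagged
in a truth log, and clean average weights are floored at 50 g so only
injected records can trip the under-50 filter. This makes the cleaning
audit exact: filter dispositions must match the truth log record by
record.

The simulator does **not** attempt real climate geography, seasonal feed
dynamics, mortality/attrition processes, disease, or correlated covariate
blocks like real bioclimatic variables exhibit. Passing tests show the
machinery recovers known structure under the stated noise; they do not
show how strong real environmental signal is.

## Problem sizes used in validation

The default pipeline configuration mirrors the emulated design: a
40 × 40 grid (21 layers, 6 regions incl. desert, 2% nodata), 1393
households over 5 breeds, biweekly weighings to week 20 (males) and 72
(females), boosting to $m_{max} = 100$ with 25 bootstrap resamples; a
full run takes under a minute on one core and is asserted byte-for-byte
reproducible from the seed. Parameter recovery is validated at 300
households on a 30 × 30 grid with all 21 covariates over 20 simulation
replicates (the three active covariates must occupy the top three
importance ranks in ≥ 90% of runs, and the stopping iteration on pure
noise must fall below the matched signal run in ≥ 90%). The boosting
engine is checked against a brute-force reference on 25 random small
instances (≤ 15 rows, 3 covariates, 10 iterations): identical selections,
risk paths within $10^{-10}$ relative.

## Known limitations

* The additive model ignores interactions between covariates and any
  spatial random effect; systematic spatial residual structure will
  inflate apparent importance of spatially smooth covariates.
* Correlations are in-sample; no household-level hold-out is performed.
* The final model is the full-data path truncated at $m_{stop}$, not a
  refit at $m_{stop}$; the two differ slightly when risk curves are flat.
* The stack container is a plain JSON grid with cell-center georeferencing
  on a regular lon/lat grid; no projections, no GeoTIFF import.
* Whether region summaries for suitability should weight cells by area or
  population is left to the `region_statistic` choice; only unweighted
  summaries are implemented.
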