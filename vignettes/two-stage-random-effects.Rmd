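---
title: "Two-stage random-effects meta-analysis: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage random-effects meta-analysis: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsremeta)
```

## The error model

A meta-dataset here is an unbalanced panel: independent groups
$i = 1, \dots, I$ (studies or independent data samples), each
contributing $J_i \ge 1$ effect-size observations $y_{ij}$ with reported
standard errors $se_{ij}$. The model decomposes every observation into
three error components around the target effect $Y$:

$$ y_{ij} = Y + \eta_i + \mu_{ij} + \varepsilon_{ij}. $$

* $\eta_i$, variance $\sigma_\eta^2$: group-level non-sampling error —
  everything a study's design, sampling frame, and specification choices
  do to *all* of its estimates (what the meta-analysis literature calls
  between-study heterogeneity).
* $\mu_{ij}$, variance $\sigma_{\mu,i}^2$: observation-level non-sampling
  error — sensitivity of a study's individual estimates to functional
  form, subsamples and similar within-study choices. Its variance may
  differ by group.
* $\varepsilon_{ij}$: sampling error. Its standard deviation is taken to
  be the published $se_{ij}$, and within a group the sampling errors may
  be correlated with a common correlation $\rho$, because estimates from
  one study typically reuse the same data.

$\rho$ is **not identified** from the meta-data and is never estimated;
the analyst sets it ($\hat\rho$) and can probe sensitivity. The package
default is $\hat\rho = 0.5$: simulation results (below) show point
estimates are unbiased regardless of the value assumed, precision is
best when the assumed value is realistic, and a moderate positive
correlation is the realistic description of multiple estimates drawn
from one dataset. All error components are mean zero; this is the
substantive identifying assumption (idiosyncratic design differences and
negligible publication selection — the latter testable with the
publication-bias tools).

## The two-stage estimator

Any convex combination of the observations is unbiased under the model;
the estimator picks the minimum-variance one, in two stages.

**Stage 1 (within groups).** The within-group covariance of
$\mu_{ij} + \varepsilon_{ij}$ is
$\Sigma_i = \mathrm{diag}(\sigma_{\mu,i}^2 + se_{ij}^2)$ with
off-diagonal $\rho\, se_{ij} se_{ik}$. The variance-minimizing convex
weights are $g_i \propto \Sigma_i^{-1} \mathbf{1}$. The implementation
computes them from the equivalent fixed-point form
$g_i = (I - B_i)^{-1} A_i$, where $A_i$ is the normalized
conditional-inverse-variance vector with conditional variances
$\sigma_{\mu,i}^2 + (1-\rho)\, se_{ij}^2$ and $B_i$ is a rank-one
correlation correction. The algebraic equivalence of the two forms
(confirmed to $10^{-8}$ over $10^4$ random groups in the test suite) is
the package's transcription check: $\Sigma_i$ is a rank-one update of
the conditional-variance diagonal, so Sherman–Morrison turns the GLS
solution into exactly this fixed point.

**Stage 2 (between groups).** Group estimates
$\hat Y_i = \sum_j g_{ij} y_{ij}$ have unconditional variances
$v_i = \sigma_\eta^2 + g_i' \Sigma_i g_i$; the overall estimate weights
them by $h_i \propto 1/v_i$. Per-observation weights are
$w_{ij} = g_{ij} h_i$, so weights sum to one within groups, across
groups, and overall.

**Variance components by the method of moments.** Within a non-singleton
group, the sample variance of $y$ over-states $\sigma_{\mu,i}^2$ by the
average sampling variance and under-states it by the sampling
covariance, so

$$ \hat\sigma_{\mu,i}^2 = s_y^2 - \frac{1}{J_i}\sum_j se_{ij}^2
   + \frac{1}{J_i (J_i - 1)} \sum_{j \ne k} \rho\, se_{ij} se_{ik}, $$

which is exactly unbiased under the model (the cross-term normalization
$1/(J_i(J_i-1))$ is forced by unbiasedness; the test suite verifies it
against a simulation oracle). Likewise
$\hat\sigma_\eta^2 = s^2_{\hat Y} - \frac{1}{I}\sum_i g_i' \Sigma_i g_i$.
No distributional assumption enters anywhere.

### Variants

* `variant = "free"`: each non-singleton group keeps its own
  $\hat\sigma_{\mu,i}^2$ (truncated at zero). Singleton groups cannot
  supply one; they receive the average of the non-singleton
  $\hat\sigma_{\mu,i}$, averaged on the $\sigma$ scale then squared
  (averaging on the variance scale is available via `fill_scale`).
  Setting singletons to zero instead would reward studies for reporting
  fewer estimates.
* `variant = "equal"`: one pooled value
  $\hat\sigma_\mu^2 = \sum_i (J_i - 1) \hat\sigma_{\mu,i}^2 \big/
  \sum_i (J_i - 1)$ for all groups — degrees-of-freedom weighting, the
  direct analogue of a pooled within-group variance. Pooling uses the
  *untruncated* per-group values and truncates once at the end:
  truncating each noisy per-group estimate first and then averaging
  would push the pooled variance far above the truth (at the base
  simulation design the inflation is larger than the parameter itself).
* `variant = "true"`: user-supplied components; only meaningful in
  simulations, where it provides the precision benchmark.

At realistic meta-analysis sizes (tens of groups, a handful of
observations each) the per-group variances of the `"free"` variant are
estimated from 1–4 degrees of freedom each and the resulting weights are
noisy; `"equal"` sacrifices the heterogeneity of $\sigma_{\mu,i}$ for
far more stable weights and is the recommended default. The simulation
harness reproduces this ordering under every correlation setting tested.

### Truncation and unbiasedness

Method-of-moments variance differences can be negative; the fitted
components truncate at zero and count truncations in `diagnostics`. A
truncated estimator is necessarily biased upward whenever the raw
statistic can go negative, so the fit also records the untruncated
statistics (`sigma_eta_sq_raw`, `sigma_mu_sq_pooled_raw`); those are the
quantities whose unbiasedness the test suite asserts. Point-estimate
unbiasedness is unaffected — any convex weights are unbiased under the
model.

### Standard errors

Two are provided. The cluster-robust (sandwich) SE treats groups as
clusters: with fitted weights,
$\widehat{se}^2 = \frac{I}{I-1} \sum_i \big(\sum_j w_{ij}(y_{ij} - \hat
Y)\big)^2$ (CR0 with the $I/(I-1)$ small-sample factor; fancier CR2-type
adjustments are out of scope). The cluster bootstrap resamples *groups*
with replacement (default $B = 2000$), re-estimating all variance
components, singleton fills and pooling inside every replicate;
replicates drawing a single distinct source group are skipped and
counted. Simulations in the test suite show the robust SE tracks the
estimator's empirical spread within 10% even when $\hat\rho$ is wrong —
the weights become merely suboptimal, while the sandwich remains valid.

## Meta-regression

With moderators $x_{ij}$, the target $Y$ is replaced by $x_{ij}\beta$
and the same weight machinery applies, with two substitutions: the
within-group variance estimator subtracts the within-group sample
variance of the fitted values from that of the effects, and the
between-group statistic uses weighted group residuals
$\sum_j g_{ij}(y_{ij} - x_{ij}\hat\beta)$. Estimation iterates
(components $\to$ weights $\to$ WLS $\hat\beta$) from $\hat\beta = 0$
until $\max|\Delta\hat\beta| < 10^{-8}$ (default `max_iter = 200`).

Because the variance truncation makes the update map piecewise, a small
fraction of datasets produce an exact two-cycle straddling a truncation
boundary. The iteration therefore carries a monotone relaxation factor,
halved whenever the fixed-point residual stops shrinking; the damped
sequence converges to the boundary point, and such fits are flagged
(`boundary_cycle`, with the residual of the undamped map recorded).
With a constant-only design no iteration happens at all: the routine
delegates to the meta-analysis fit, so the two agree bitwise.

Specifications `s0`–`s6` cover the standard moderator sets for VSL
syntheses (stated-preference and median-statistic indicators, data year,
income, and interactions). Year and income are centered at their
observation means so the constant is the predicted effect for a
revealed-preference mean observation at average year/income; slopes are
invariant to the centering. PET/PEESE enter the meta-regression as
added regressors ($se$, $se^2$) rather than as a separate procedure.

Reported fit statistics: a weighted $R^2$ (share of the $w$-weighted
variance of $y$ around its weighted mean explained by the fit — by this
definition a constant-only model explains nothing) and $RCV^2$, the
cross-validated analogue computed from leave-one-out residuals where
*every* fold refits the entire iterated estimator, weights included.
The LOO unit is the single observation by default; group-level LOO is
available (`loo_unit = "group"`) since observations within a group are
dependent, and the choice is recorded on the result. $RCV^2$ uses
unweighted residual and total sums of squares, matching its use as a
comparable model-selection statistic across specifications.

The income elasticity of the synthesized effect is the derivative of the
predicted effect with respect to income — including interaction terms,
evaluated at the mean of the interacting indicator — times mean income
over the prediction at the moderator means.

## Comparator estimators

The Monte Carlo harness needs self-contained implementations of the
usual alternatives, under one interface (`meta_dataset` in,
`meta_estimate` out, convex weights): unweighted simple and group means;
fixed-effect inverse-variance; DerSimonian–Laird on singleton data, with
a composite-variance aggregator for dependent observations (group mean
with variance $\frac{1}{J^2}(\sum se^2 + \hat\rho \sum_{j\ne k} se_j
se_k)$); a correlated-effects working model (group-constant sampling
variance, DL-type $\tau^2$ on the composites, equal within-group
splits); a hierarchical-effects working model (identical to the
two-stage estimator with `"equal"` pooling and $\rho = 0$); and a
multilevel REML estimator with known block sampling covariance and a
single between-group variance, profiled and optimized on
$[0, 100\,\mathrm{var}(y)]$. These follow the published working models
from the robust-variance-estimation and random-effects literatures; they
are not numerical replicas of any particular software package, and the
test suite cross-checks the DL, trim-and-fill, and REML routines against
an independent implementation (`metafor`) where one exists.

## Publication bias

**Trim-and-fill** iterates {center via the supplied pooling estimator
(fixed-effect inverse-variance by default) → estimate the suppressed
count $k_0$ from the signed ranks of deviations (L0 by default, R0
available) → trim the $k_0$ most extreme effects on the heavy side}
until $k_0$ stabilizes, then fills mirror-image pseudo-observations and
re-pools. `side = "auto"` infers the heavy side from the sign of the
third central moment about the pooled center; an explicit side can (and
for a directional hypothesis should) be given. For a two-stage fit the
correction operates on the *group-level* funnel
$(\hat Y_i, \hat v_i)$ by default — within-group correlation breaks the
funnel's independence assumption at the observation level — with an
observation-level mode behind a flag.

**PET-PEESE**: the precision-effect test regresses effects on a constant
and $se$ (inverse-variance weights by default) with cluster-robust
inference; a slope distinguishable from zero at two-sided 5% signals
selection, in which case the corrected estimate is the intercept of the
regression on $se^2$ — the extrapolation to an infinitely precise study.
When the test does not fire the uncorrected weighted mean is reported
(or the PET intercept, per `fallback`); the decision path is recorded.

## The synthetic-data generator and what the simulations show

`gen_meta_dataset()` draws from exactly the three-component model: per
group, $J_i$ uniform on an integer range, $\sigma_{\mu,i}$ uniform on a
range (so within-group variances are heterogeneous across groups —
which makes the `"equal"` variant deliberately misspecified, a binding
restriction it must survive), $\eta_i$ normal; per observation, $se$
uniform, $\mu$ normal, and sampling errors jointly normal with
exchangeable correlation $\rho$ built from a shared group factor. The
default design cell — true effect 10, $I = 20$, $J \sim U\{1..5\}$,
$\sigma_\eta = 1$, $\sigma_{\mu,i} \sim U(0.5, 1)$,
$se \sim U(0.5, 5)$, $\rho = 0.5$ — is the low-variability corner of
the evaluation grid, which varies $I \in \{20, 60\}$,
$J \in \{1..5, 1..15\}$, $\sigma_\eta \in \{1, 3\}$,
$\sigma_\mu \in \{U(0.5,1), U(0.5,3)\}$ and
$(\rho, \hat\rho) \in \{0, 0.5\}^2$. Normality is a generator choice,
not an estimator assumption; a heavier-tailed $\mu$ is a one-line
change for robustness studies.

What passing simulations do and do not establish: they confirm
unbiasedness, the precision ordering of the variants, robust-SE
calibration, and variance-component recovery *under the model*,
including misspecified $\hat\rho$ and the binding `"equal"` restriction.
They cannot speak to violations the generator does not produce —
non-zero-mean non-sampling errors (systematic bias in a literature),
selection on significance (addressed separately by the bias tools), or
heavy-tailed errors.

`run_experiment()` uses common random numbers (the same datasets for
every estimator within a trial, from per-trial seeds spawned off one
master seed) and summarizes bias, the across-trial SD of estimates (the
estimator's empirical standard error), mean robust SE, and normalized
precision $(\widehat{se} - se_{\min})/se_{\min}$ against the
known-components benchmark, whose normalized precision is zero by
construction.

Problem sizes in the shipped tests are chosen to keep the default suite
in the minutes range: full 2,000-trial runs for the headline
unbiasedness/precision checks at the base cell, 400–800 trials for
orderings, calibration and component-recovery checks, and $10^4$ random
groups for the weight-identity oracle; `scripts/acceptance.R` re-runs
the 2,000-trial base-cell experiment end to end.

`make_epa_like_fixture()` generates a clearly synthetic dataset with the
composition of the demonstration application (46 hedonic-wage
observations in 9 groups, 25 quasi-experimental in 1 group, 42
stated-preference in 9 groups; revealed-preference studies report means
only) for tests and examples. It is *not* the real application data,
and nothing in the package asserts the application's numerical results
against it; the replication test instead looks for the original dataset
at `inst/extdata/epa_vsl_meta.csv` and reports its absence otherwise.

## Jackknife model averaging

Given candidate meta-regression fits, the averaging weights minimize the
sum of squared leave-one-out prediction residuals of the weighted
average over the probability simplex — a convex QP, solved with a dense
QP solver and cross-checked in tests against an independent
projected-gradient solver (agreement to $10^{-6}$ required). Flat
directions (duplicate or collinear candidates) are resolved toward the
minimum-norm weights by a tiny ridge term, so duplicates share weight
equally. The standard candidate set crosses specifications `s0`–`s6`,
the two feasible variance variants, and bias correction (none or the
$se^2$ regressor): 28 models. The quantity combined for a balanced
synthesis is the regression constant plus half the stated-preference
coefficient, with centered moderators at their means.

## Numerical notes and limitations

* Within-group systems are solved by dense factorization; groups in
  meta-analyses are small (tens of observations at most).
* $(I - B_i)$ can be singular only in degenerate corners (e.g.
  $\rho \to 1$ with equal standard errors); the solver reports the
  offending group.
* Negative $\rho$ is accepted when the implied exchangeable correlation
  matrix is positive definite for every group size present.
* Weight normalization is enforced to $10^{-10}$ and checked in tests at
  all three levels.
* The estimator assumes reported standard errors are the truth;
  measurement error in $se_{ij}$ is not modeled.
* Group membership is taken from `group_id` as given; studies sharing an
  underlying primary dataset are not automatically merged, and the
  independence of groups is the user's responsibility.
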