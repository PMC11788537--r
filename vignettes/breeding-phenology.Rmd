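---
title: "Estimating breeding-season phenology and its climate drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating breeding-season phenology and its climate drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Citizen-science portals accumulate large numbers of bird observations, a
minority of which carry breeding-evidence codes (courtship, nest building,
feeding nestlings, ...). For an alpine species whose breeding window is
short and strongly weather-dependent, these records contain enough signal
to reconstruct, year by year, *when* the population was breeding — without
any structured monitoring. `snowphen` implements that reconstruction and
the downstream climate-sensitivity analysis as a single reproducible
pipeline:

1. classify each observation into a binary state — *likely breeding*
   (courtship-level code or higher, inside May 1–Aug 31) vs *nonbreeding*;
2. fit, per year, a hierarchical binomial GAM of the state against day of
   year, giving a posterior for the expected proportion of likely-breeding
   observations $p(d)$ per biogeographic region;
3. extract season start, end, and duration as threshold crossings of
   $p(d)$;
4. summarise snowmelt timing and duration from daily snow-cover fractions;
5. scan sliding climate windows for the periods whose mean temperature or
   number of precipitation days correlate most strongly with the phenology
   metrics;
6. quantify the effects with linear mixed models, and track the change of
   breeding-season temperature across years.

A seeded synthetic-data generator with planted effects gives every stage a
parameter-recovery test surface.

## The phenology model

For one year, with observations indexed by day of year $d$ and region $r$,
the state $y_i \in \{0, 1\}$ is modelled as

$$y_i \sim \mathrm{Bernoulli}(p_i), \qquad
\operatorname{logit} p_i = \beta_0 + f(d_i) + f_{r(i)}(d_i),$$

where $f$ is a global smoother shared by all regions and $f_r$ are
per-region deviation smoothers. All smoothers use a **cyclic cubic
regression spline** basis over days 60–304 (Mar 1–Oct 31): the function and
its first two derivatives match at the domain ends, which ties the fitted
curve to a common (near-zero) level in March and October, where breeding
activity is absent by construction. The basis is parameterized by its
values at the knots; its penalty is the integrated squared second
derivative, $S = D^\top B^{-1} D$ in the standard cyclic-spline matrices,
verified in the tests both against a numeric integral of $f''^2$ and
against the field-standard construction in `mgcv`.

The hierarchy follows the usual global-plus-group-smoother construction:
the global smoother is sum-to-zero constrained (the intercept carries the
overall level); each region's deviation smoother shares the same basis and
one common roughness penalty, and the per-region constants — the roughness
penalty's null space — carry their own shared level penalty, acting as
random region intercepts. Keeping the level penalty separate from the
roughness penalty matters: a single overlapping ridge over whole deviation
blocks lets REML collapse all regional structure to zero when the
region-level signal is modest, whereas the split penalties estimate the
between-region level variance on its own scale. A region with few or no
observations still inherits the global curve.

**Inference.** Smoothing parameters are estimated by REML via `mgcv`
operating on the package's own design and penalty matrices
(`phenology_design()`), so the model is exactly the one described above.
One guard rail: with only four regions the REML (empirical-Bayes) estimates
of the deviation penalties can diverge, collapsing the hierarchy to
complete pooling and erasing real regional differences — the small-group
boundary pathology familiar from variance-component estimation. The
default therefore caps the deviation roughness and level penalties at
weakly informative values (`sp_cap`), playing the role that weakly
informative priors on smoother scales play in a fully Bayesian fit; the
global smoother's penalty is never bounded, and plain REML is one argument
away.
Posterior draws of the curve come from one of two engines:

* `method = "laplace"` (default): draws from the Gaussian approximation to
  the posterior at the penalized-likelihood optimum. Fast and
  deterministic given a seed; adequate at the several-hundred-observations
  scale of a season.
* `method = "mcmc"`: the reference mode — an independence
  Metropolis–Hastings sampler on the exact penalized-likelihood posterior
  (smoothing parameters fixed at their REML estimates), default 4 chains
  × 8000 iterations thinned by 4, with split-chain Gelman–Rubin
  diagnostics; any $\hat R \ge 1.01$ flags the fit non-converged.

The contract both engines honour is "at least 1000 posterior draws of
$p(d)$ on a daily grid". Residual spatial or temporal autocorrelation is
not modelled; `residuals()` on a fit supports the diagnostic checks that
motivate that choice.

**Basis dimension.** The default is 12 knots (11 free coefficients) over
the 245-day domain, about 20-day flexibility — enough for the
rise–plateau–fall shape of a single breeding season while leaving real
wiggliness to the penalty. It is configurable (`n_knots`); sensitivity to
this choice is far below the threshold-choice sensitivity quantified by
`threshold_sensitivity()`.

## Threshold metrics

Start is the first grid day on which $p(d)$ exceeds the threshold $\tau$
(default 5%); end is the first day after the post-start maximum on which it
drops below $\tau$; duration is their difference. Point estimates use the
**posterior-mean curve** (stable, and consistent with defining the metrics
on the *expected* proportion); the same rule applied per draw yields 95%
intervals. Anchoring the end search after the maximum keeps early dips of
wiggly curves from truncating the season. Crossings are reported as integer
days — the data are daily, and sub-day interpolation would suggest
precision the data do not carry. Curves that never exceed $\tau$ give an
*undefined* flag rather than an error; curves still above $\tau$ at the
domain end are censored there and flagged.

The threshold-sensitivity analysis recomputes durations at 1%–12% and
correlates each vector with the 5% reference; high correlations mean the
conclusions do not hinge on the 5% convention.

## Snow metrics

From each region-year's daily snow-cover-fraction series: melt **timing**
is the first day at or after peak cover with cover at 50% *absolute*
coverage or below; melt **duration** is the number of days between the
series dropping below 95% and below 5% *of its seasonal maximum* (relative
thresholds, because full cover is not reached in every region-year). "After
melt onset" is operationalized as "after the day of maximum cover" — the
one unambiguous anchor available. Threshold comparisons are `<=` for the
50% timing and strict `<` for the relative thresholds, both configurable;
ties at exactly the threshold are a knife-edge the daily data essentially
never produce.

## Sliding-window scan

Candidate windows have both endpoints on a 2-day grid anchored at the
search-range start, minimum length 7 days: Apr 1–Jun 30 for the season
start, Apr 15–Aug 15 for the end. Per window the climate is summarised as
the mean temperature or the number of precipitation days (≥ 1 mm), and the
Pearson correlation $r$ with the phenology metric is computed over pooled
year × region points (up to 64). Because hundreds of windows are scanned,
some $|r|$ are large by chance; each correlation therefore carries its
large-sample standard error $\sqrt{(1-r^2)/(n-2)}$ and only windows whose
symmetric 95% interval excludes zero count as *certain*. The critical
window is the certain window maximizing $|r|$ (ties: shorter window, then
earlier opening). The null-calibration test in the suite verifies that with
a response independent of climate the certain fraction matches the nominal
filter level — the multiple-testing caveat embodied as a test.

Point estimates (not posterior draws) of start/end feed the scan; phenology
uncertainty re-enters later through the mixed models' residual variance.
Pooling across regions (rather than scanning per region) matches the
spatial scale at which the climate series are summarised; per-region
scanning can be had by subsetting the metrics table.

## Effects models

For each response (start, end, duration) a Gaussian LMM with random
intercepts for year and region:

$$y_{tr} = \beta_0 + \sum_j \beta_j x_{j,tr} + u_t + v_r + \varepsilon_{tr}.$$

Predictors are centred at their analysis-sample means in both reported
parameterizations; *standardized* slopes divide additionally by the sample
SD. This makes `standardized = unstandardized × SD(x)` an exact identity
for every term (the interaction column scales by the product of SDs) and
leaves the intercept in day-of-year units. A temperature × precipitation
interaction is retained by a reproducible proxy for a visual judgement:
keep it when the 80% interval of its standardized coefficient excludes
zero (`retain_interaction = "auto"`; `"always"`/`"never"` available).

Fitting is REML via `lme4`; intervals come either from 8000 draws of the
Gaussian approximation to the fixed-effect posterior (engine `"sim"`,
default, organised as 4 chains × 2000 with warmup discarded) or from Wald
intervals (engine `"reml"`). Random-effect SDs are reported as REML point
estimates; with only 4 regions they are weakly identified and fits flagged
`singular` should be read accordingly. `scenario_contrast()` compares
covariate scenarios through the joint coefficient distribution with random
effects at zero, warning (not failing) on extrapolation beyond the observed
covariate range.

Temperature trends are ordinary Gaussian linear regressions of an annual
mean-temperature series on year — once for the breeding-season means
(season limits taken from the estimated phenology of a reference region)
and once for fixed May–August means — reporting the slope and the implied
total change over the span.

## The synthetic generator

`simulate_study()` emulates the study conditions: 16 years (2006–2021) × 4
regions × 200 observations per region-year (≈ 12,800 rows), with

* temperature = seasonal sinusoid (annual mean 2 °C, amplitude 9 °C, peak
  day 200, region offsets −0.5…+1.5 °C) + linear warming trend
  (0.0533 °C/yr, i.e. +0.8 °C over the 16-year span) + yearly anomaly
  (SD 0.8 °C) + week-scale AR(1) weather spells (correlation length 12
  days; a regionally shared series per year with SD 1.2 °C plus a
  region-specific one with SD 0.8 °C) + daily noise (SD 2 °C). The spells
  matter structurally: without sub-seasonal anomalies every candidate
  window would carry the same year-level signal and no window would be
  identifiable — with them, windows a few weeks apart have genuinely
  different anomalies, as real weather does;
* precipitation = Bernoulli(0.5) occurrence × Gamma(0.8, scale 8) amounts,
  a wet alpine spring-summer regime whose 11-day window counts span about
  4–9 precipitation days;
* snow cover = deterministic logistic decline through a planted 50%-cover
  day (mean day 150, between-year SD 8 days, coupled −3 days/°C to the
  yearly temperature anomaly) with a planted 95%→5% melt span (mean 45
  days, SD 6 — within the plausible 23–77-day range of alpine melts);
* true phenology: start = 142 + (−6 days/°C) × start-window temperature
  anomaly (days 125–161) + (+3.7 days/day) × precipitation-day anomaly
  (days 109–119) + year intercept (SD 6) + region intercept (SD 8) +
  residual (SD 3); end = 236 + (−1.8 days/°C) × end-window anomaly (days
  165–181) + year (SD 4) + region (SD 2.5) + residual. The implied mean
  duration is 94 days.

The latent observation curve is a double logistic scaled to a plateau
`p_max = 0.35` and anchored so that it crosses the threshold $\tau$
*exactly* at the true start and end — "true start" is then well-defined in
precisely the metric the pipeline estimates, so recovery error is
estimation error, not definitional mismatch. One consequence of exact
anchoring on a daily grid: the first day *exceeding* $\tau$ is the day
after the crossing, a deliberate one-day convention absorbed by the same
offset at the season end (durations are unbiased). Observation dates are
uniform over Mar–Oct by default with a configurable midsummer effort
bulge.

What the generator does **not** emulate: spatially explicit observation
effort, observer heterogeneity and misclassification of breeding codes,
seasonal gaps in reporting, autocorrelated weather beyond the yearly
anomaly, and double-brood bimodality in $p(d)$. Passing recovery tests on
synthetic data therefore demonstrates the estimator chain is correct and
well-calibrated under the planted model, not that real citizen-science
data meet its assumptions.

## Numerical choices and degenerate inputs

* Anchoring shifts of the latent curve are solved by fixed-point iteration
  to $10^{-10}$ days; it converges whenever `p_max > tau` (enforced:
  otherwise the season would be undetectable by construction).
* Single-state years (e.g. no likely-breeding record) are fitted anyway
  and flagged `degenerate`; the curve collapses towards 0 (or 1), and the
  metrics come out undefined/censored rather than erroring.
* Windows with incomplete daily series in some year × region drop those
  cells with a warning; windows with fewer than 3 complete pairs or
  zero-variance summaries are omitted from scans.
* Leap years keep natural day-of-year numbering; the 1-day offset is far
  below phenological noise.
* Observations with breeding codes below the cut (or absent) count as
  nonbreeding rather than being excluded: the two states are exhaustive.

## Problem sizes used by the test suite

The suite exercises the full study scale where the property demands it and
smaller scales elsewhere, as a deliberate accuracy/runtime trade-off: one
16-year × 4-region × 200-obs recovery run for the phenology and
threshold-sensitivity checks; 100 generator replicates for window
localization and 50 for slope-recovery coverage, both on the generator's
true phenology tables (GAM estimation error is covered by the recovery
run); 200 null-response scans over one fixed climate realization for the
certainty-filter calibration; 100 replicates for trend-coverage. The
window-recovery and calibration replicates deliberately reuse closed-form
truth rather than re-fitting 1600 GAMs; the full chain
(generator → GAM → metrics → scan → LMM) is executed end-to-end in the
pipeline tests and by `scripts/acceptance.R`.

## Known limitations

* Threshold crossings are information-hungry. At the study-like default of
  200 observations per region-year (~22 of them likely breeding), the
  per-region start day is identifiable only to about a week: even an
  oracle that knows the true curve family and estimates nothing but its
  two shift parameters by maximum likelihood shows a start-day error SD
  near 9 days on such data. The acceptance run's recovery numbers (mean
  absolute errors of roughly 8 days for the start and 5 for the end at
  study scale) are at that floor, not an estimator defect; REML partial
  pooling trades essentially all of the between-region start variation for
  variance reduction at this sample size. Per-region precision improves
  roughly with the square root of effort.
* The Laplace engine understates posterior tail uncertainty for regions
  with very few likely-breeding records; use `method = "mcmc"` when the
  intervals matter more than runtime.
* The certainty filter controls the per-window error rate, not the
  familywise one; with ~1000 correlated windows the selected window's
  $|r|$ is optimistically biased (winner's curse). The LMM slopes are
  conditioned on the selected window, as in the original design.
* Random-effect SDs from 4 regions are weakly identified; treat the
  region SD as descriptive.
* First and second broods are not separated: a bimodal season yields one
  start/end pair spanning both peaks.
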