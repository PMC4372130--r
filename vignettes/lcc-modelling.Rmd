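---
title: "Stochastic modelling of land cover change with lccsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modelling of land cover change with lccsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lccsim)
```

## The model

`lccsim` models a landscape of three categorical states — mature forest,
regenerating (secondary) forest, and deforested (non-forest) land — observed
as a dated series of rasters sharing one nodata mask. Change is decomposed
into three independent transitions: forest to deforested (FtoD),
regeneration to deforested (RtoD), and deforested to regeneration (DtoR).
For a cell $x$ in the source class of a transition at time $t$, the
probability of making that transition over one calibration interval is
logistic in a linear predictor $\kappa_{x,t}$:

$$P_{x,t} = \frac{1}{1 + e^{-\kappa_{x,t}}}, \qquad
  \kappa_{x,t} = \beta_0 + \sum_j \beta_j\, c_{j,x,t},$$

where the covariates $c_j$ are the landscape drivers. As $\kappa$ runs from
$-\infty$ to $+\infty$ the probability runs from 0 to 1. Nine covariate
layers are supported:

* **static** — Euclidean distance (metres) to the nearest road, river and
  settlement cell, and a 0/1 protection indicator; computed once per
  landscape;
* **dynamic** — the *contagion* of deforestation and of regeneration (the
  proportion of valid neighbours in a square Moore neighbourhood of
  half-width `radius`, centre excluded, currently in the state), and three
  land-use history metrics: *PALU* (calendar years the cell spent deforested
  before its most recent abandonment), *ARF* (years since that abandonment,
  for currently regenerating cells) and *FC* (number of observed clearance
  events). Dynamic layers are recomputed from the current map and trajectory
  at every simulation step.

The history metrics are offered only to the RtoD candidate set: clearance
history is informative where established land use recycles regenerating
plots, while FtoD and DtoR act on cells for which these metrics are zero by
construction almost everywhere.

Given a calibration pair of maps $n$ years apart, the cells of the source
class at the first date define the likelihood: $Z_x = 1$ if the cell is in
the transition's target class at the second date, $Z_x = 0$ if it stayed in
the source class, and cells that moved to the third class are excluded from
that transition. The Bernoulli log-likelihood is

$$\ell = \sum_x \log\{ Z_x P_x + (1 - Z_x)(1 - P_x) \},$$

with probabilities clamped to $[10^{-12}, 1-10^{-12}]$ so saturated
predictions stay finite.

## Fitting: Metropolis–Hastings and stepwise selection

Coefficient posteriors are sampled by a component-wise Gaussian random-walk
Metropolis sampler under independent flat box priors ($\pm 50$ on the
standardised-covariate scale, effectively uninformative). Defaults: 20,000
iterations, the first half discarded as burn-in, per-coefficient step sizes
adapted only during burn-in (windows of 50 proposals nudged toward ~40%
acceptance), and the post-burn-in chain thinned to 1,000 retained draws.
Covariates are standardised internally for sampler conditioning and the
draws are back-transformed, so reported coefficients are per natural unit
(per metre for distances) — with metre-scale distance layers the
coefficients of interest are of order $10^{-3}$–$10^{-5}$. Two numerical
details matter:

* the likelihood is evaluated in the stable form
  $\sum_g y_g \kappa_g - w_g \log(1 + e^{\kappa_g})$ after collapsing cells
  with identical covariate rows into weighted binomial groups; this is an
  exact reformulation that makes chains on discrete covariates (contagion,
  protection) orders of magnitude faster;
* chains are reproducible: the sampler consumes R's RNG stream under the
  seed recorded in the `chain_config`.

A warning is raised if the post-burn-in acceptance rate leaves
$(0.01, 0.9)$.

Covariates are chosen per transition by forward stepwise search scored on
held-out likelihood: the source cells are split 50/50 once per run (seeded),
each step refits every candidate addition on the training half and evaluates
the test half's log-likelihood at the posterior-mean coefficients, and the
search stops when no addition improves the test likelihood. Scoring at the
posterior mean is a deliberate choice — the selection criterion needs a
single representative parameter value, and the posterior mean is the
estimate the package reports; using one split across steps keeps test
likelihoods comparable between steps. Ties break toward fewer covariates,
then candidate order. A split that leaves either half without a single
observed transition is an error naming the transition, not a silent fit.

## Simulation

`lcc_simulate()` propagates the landscape forward in steps of one
calibration interval. Each of `n_iterations` (default 100) iterations draws
one joint row per transition from the retained posterior samples — joint
rows preserve within-model coefficient correlations, which independent
per-coefficient draws would destroy — and then advances the map `n_steps`
times. Within a step the update is synchronous: every source cell flips
independently with its probability computed from the incoming map, and the
dynamic covariates are recomputed only between steps, from the simulated
trajectory (so contagion spreads and the history metrics grow with the same
carried-forward convention used in calibration). Nodata cells never change.
Each iteration runs on its own RNG stream derived from `(seed, iteration)`,
so iterations are individually reproducible. The iteration spread therefore
carries both Bernoulli event noise and coefficient uncertainty.

## Validation: perfect match

Change between two maps is coded 1 (forest→deforested), 2
(regeneration→deforested), 3 (deforested→regeneration), 0 otherwise. For
each iteration the *perfect match* is the percentage of observed changed
cells whose code is predicted exactly; the denominator is the count of
observed changed cells only. Two consequences are worth stating plainly:
cells that never changed cannot inflate the score, and predicted change at
observed-unchanged cells is not penalised — the metric measures the ability
to hit observed change, not false-positive restraint.

## Calibration-window experiments

A `model_design` is a calibration pair (start, end). Simulation proceeds
from the *start* map in steps of `end - start` years, so the design's
prediction years are `start + k*(end - start)`; the calibration end map is
step 1, and the time step of a target year is `(target - start) / length`.
A design can be validated at any later observed map its prediction sequence
hits. `enumerate_designs()` lists every design that lands exactly on a
target year; `run_design_grid()` executes the full grid (stepwise fits,
simulation, perfect match per validation year).

`anova_decomposition()` fits the perfect-match scores against initial year,
transition length, time step and validation year as *continuous* covariates
(1 df per term) with sequential (Type I) sums of squares, in the order:
main effects, then the two-way interactions initial:length, initial:step,
initial:validation, length:validation, step:validation, then the three-way
and four-way interactions. The length:step interaction is excluded by
construction: `length * step = validation_year - start_year` on every
admissible design, an exact linear combination of terms already present.
Covariates are centred before products are formed — calendar-year-scale
products are otherwise numerically degenerate — which leaves the sequential
decomposition identity (term SS sum to the total SS) intact. Any remaining
rank deficiency is an error naming the collinear terms.

`univariate_parameter_series()` fits single-driver models on every adjacent
pair of dates, and `trend_test()` runs the ordinary least-squares trend
regressions (slope, $t$, $R^2$, df $= n-2$, two-sided $p$) used to ask
whether a driver's effect drifts through time.

## The synthetic landscape generator

`synthetic_scenario()` + `generate_truth_series()` produce data with the
statistical structure the models assume, by construction: parametric driver
geometry (two roads, a meandering river, one settlement, a protected
rectangle covering ~25% of the landscape, and a small water body as a shared
nodata mask), and a land cover series simulated *annually* from known
coefficients through exactly the same step function, covariate definitions
and carried-forward history conventions the fitting code uses — recorded
only at the scenario's observation dates, so the series has realistic gaps.

Defaults are chosen to resemble a smallholder colonisation frontier at
Landsat scale: a 100 × 100 grid of 30 m cells, 20 observation dates over
1986–2011, an initial landscape of forest with a few deforested nuclei, and
annual-step truths in which clearing of mature forest is strongly contagious
(coefficient 4), concentrated near roads (−8×10⁻⁴ per metre) and suppressed
inside the protected area (−1.5) around a baseline of about 2% per year;
clearing of regeneration is milder and responds to clearance history; and
abandonment is contagious and biased away from roads. These settings give
multi-decade trajectories in which forest declines steadily while
regeneration and deforested land accumulate — dynamics in the ballpark of
frontier municipalities — without attempting to replicate any particular
region's numbers.

What the generator does *not* emulate: classification error in the maps
(states are observed without noise), road-network growth (features are
static), georeferencing, spatially autocorrelated suitability beyond the
built-in drivers, and rate variation beyond what the supplied (possibly
time-varying) coefficients encode. Tests passing on synthetic data
demonstrate that the estimation and simulation machinery is correct and
well calibrated under the model's own assumptions; they do not certify
performance on real imagery, where misclassification and unmodelled drivers
will loosen every bound.

## Problem sizes and test design

The test suite exercises the pipeline at desk scale, as the package's own
choice of experimental design: parameter recovery refits 100 × 100
single-interval truths (roughly 10,000 source cells) under 20 seeds per
transition at the default chain settings, counting the fraction of
coefficient/interval coverage checks that succeed (nominal 95% intervals,
threshold 90%); stepwise recovery plants one active driver among five
candidates at ~5,000 cells over 20 seeds; posterior-predictive checks
simulate 100 iterations two steps ahead and require ≥90% of the
seed × step envelope checks to cover the observed event counts; and the
calibration-drift experiment uses an 80 × 80 landscape whose deforestation
regime switches from a sparse road frontier to an intense river-driven
regime midway, comparing pre- and post-switch calibration designs at a
common validation year with a sign test over 5 seeds, against a stationary
control. The drift construction deliberately changes both the active driver
and the rate: a pure driver swap at constant rate is largely masked by the
perfect-match metric's preference for long simulation horizons, which
accumulate more matchable change.

## Known limitations

* The sampler is a random-walk Metropolis scheme; posteriors with strong
  covariate collinearity will mix slowly. Standardisation mitigates but
  does not remove this.
* Constant covariate layers (e.g. history metrics before any history
  exists) are left unstandardised and are unidentifiable; the stepwise
  search will never select them, but fixed-spec fits including them return
  prior-like marginals for those coefficients.
* One 50/50 split per stepwise run means selection noise is not averaged
  over splits; rerunning with another `split_seed` quantifies it.
* The perfect-match metric does not penalise false-positive change and
  mechanically favours long horizons; comparisons across designs should
  hold the validation year fixed, as `run_design_grid()` output allows.
* GeoTIFF output is plain single-band TIFF with a JSON sidecar for year and
  cell size; no coordinate reference system is written.
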