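# lccsim

Stochastic, spatially explicit modelling of land cover change among three
classes — mature forest, regenerating (secondary) forest, and deforested
land — for landscape ecologists studying deforestation frontiers and for
modellers who want to know how much their predictions depend on *when* a
model was calibrated.

The package models three transitions independently (forest→deforested,
regeneration→deforested, deforested→regeneration). For a source-class cell
*x* at time *t*, the transition probability over one calibration interval is
logistic:

    P(x,t) = 1 / (1 + exp(-kappa(x,t))),
    kappa(x,t) = b0 + sum_j b_j * c_j(x,t)

with drivers *c_j*: distance to roads, rivers and settlements (metres),
protection status, neighbourhood contagion of deforestation/regeneration,
and — for the regeneration→deforested transition — land-use history metrics
(PALU, ARF, FC). Coefficients get posterior distributions by
Metropolis–Hastings sampling of the Bernoulli likelihood

    l = sum_x log{ Z_x P_x + (1 - Z_x)(1 - P_x) },

covariates are selected per transition by forward stepwise search scored on
held-out (50/50 split) likelihood, and a forward simulator applies the three
fitted transitions as independent Bernoulli draws per cell, recomputing the
dynamic covariates between steps and drawing one joint posterior coefficient
row per transition per iteration (default 100 iterations), so prediction
envelopes carry parameter uncertainty. Predictions are scored by *perfect
match*: the percentage of observed changed cells whose exact transition code
is predicted. Calibration-window experiments (`enumerate_designs()`,
`run_design_grid()`, `anova_decomposition()`) quantify how calibration year,
transition length, time step and validation year drive that score, and
`univariate_parameter_series()` + `trend_test()` track temporal drift in
driver effects.

A synthetic-landscape generator (`synthetic_scenario()`,
`generate_truth_series()`) creates driver geometry and ground-truth map
series from known coefficients through the same simulation machinery, so the
whole pipeline is testable end to end without any external data.

## Worked example

Generate a synthetic 100 × 100 landscape observed at 20 dates (1986–2011),
fit the forest→deforested transition on the 1995–1996 pair by stepwise
selection, simulate 100 stochastic iterations three years forward, and
validate against the observed 1998 map:

```r
library(lccsim)

scn    <- synthetic_scenario(seed = 7)
series <- generate_truth_series(scn)
series
#> <lc_series> 20 dates 1986-2011, 100 x 100 cells

initial <- series$grids[[match(1995, series$years)]]
final   <- series$grids[[match(1996, series$years)]]
history <- build_series(series$grids[series$years <= 1995])
stack   <- assemble_stack(initial, history, scn$features, 1995)

fit <- forward_stepwise("FtoD", default_candidates()$FtoD, initial, final,
                        stack, chain = chain_config(seed = 2), split_seed = 3)
fit
#> <predictor_spec FtoD> kappa ~ 1 + protected + contagion_defor + dist_roads
#>   train ll -304.54, test ll -364.62 (split seed 3)
#> <coef_posterior> 1000 draws, acceptance 0.37
#>       (Intercept) protected contagion_defor dist_roads
#> mean       -4.304   -1.3160           4.815 -0.0007212
#> 2.5%       -4.899   -2.3900           3.269 -0.0015320
#> 97.5%      -3.762   -0.3722           6.282  0.0001093
```

The selection recovered the generator's three true drivers, and every true
coefficient (−4, −1.5, 4, −8×10⁻⁴) lies inside its 95% credible interval:
deforestation here is contagious, clusters near roads, and is suppressed
inside the protected area.

```r
sim <- lcc_simulate(initial, list(FtoD = fit, RtoD = NULL, DtoR = NULL),
                    scn$features, history = history,
                    config = sim_config(n_iterations = 100,
                                        transition_length = 1, n_steps = 3,
                                        seed = 11))
validate_simulation(sim, initial,
                    series$grids[[match(1998, series$years)]], 1998)
#> <perfect_match> mean 6.42% over 100 iteration(s), 632 observed changed cells
```

The 6.4% reads low because this minimal run freezes the other two
transitions: the 632 observed changed cells include regeneration and
re-clearance events this simulation never attempts, and cell-exact spatial
prediction of stochastic change is intrinsically hard. The full pipeline
(all three transitions fitted; see the acceptance script) reaches ~30% on
the same kind of landscape.

A command-line front end with `synth | fit | simulate | validate | designs |
trends | anova` subcommands lives at `inst/cli/lccsim.R`:

```sh
Rscript inst/cli/lccsim.R designs --years 1991,1995 --target 2011
```

## Layout

* `R/` — grid I/O and the shared-mask data model (`grids_io`), covariates
  (`covariates`), the statistical core (`transition_model`), the simulator,
  validation, the experiment engines, the synthetic generator, and the CLI
  dispatcher.
* `src/` — the compiled Metropolis–Hastings sampler.
* `vignettes/lcc-modelling.Rmd` — the model, its assumptions, numerical
  choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites.
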