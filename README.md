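# c14demog

Demographic inference from radiocarbon time-frequency data.

Archaeological `14C` date inventories are widely used as a population
proxy under the *more dates – more people* assumption: periods that left
more datable material were, all else equal, more densely populated. This
package implements the full inferential chain used in that literature,
for archaeologists and palaeodemographers who want to move beyond visual
inspection of summed probability distributions (SPDs):

- **Calibration** of conventional radiocarbon ages (CRAs) against
  IntCal-format curves, with optional marine reservoir corrections
  (ΔR ± σ).
- **Spatial and temporal binning** — DBSCAN clustering of sites
  (great-circle distances, ε in km, minPts = 1) and complete-linkage
  grouping of CRAs within clusters (cut height *h*) — so over-dated
  contexts do not dominate the record.
- **SPDs** with within-bin normalization, and the thinning rule used for
  model fitting (smallest-error date per bin, minimum calibrated window
  mass 0.5).
- **Mark-permutation tests** comparing the SPD *shape* of a labelled
  subset (e.g. millet-associated dates, or a coastal/inland split)
  against random relabellings, with pointwise envelopes and a global
  p-value.
- **A Bayesian truncated double-exponential growth model**: the
  probability of sampling a date from calendar year *t* inside a window
  `[b, a]` (cal BP, `a` old, `b` young) is

  ```
  p_{t = a - i} ∝ ∏_{k=1}^{i} (1 + r(t_k)),   r(t) = r1 if t > c, else r2
  ```

  a cumulative product of annual growth factors whose rate switches from
  `r1` to `r2` at the change point `c`; with `r1 = r2 = r` it reduces to
  the classic `(1 + r)^i` exponential. The model is fitted by MCMC with
  one latent calendar age per date (Metropolis-within-Gibbs, adaptive
  proposals), priors `r1, r2 ~ Normal(0, 0.0004)` and
  `c ~ TruncNormal(5000, 1000)` on `[3000, 7000]`, and ships with
  split-chain Gelman–Rubin and Geyer-ESS diagnostics plus prior/posterior
  predictive SPD envelopes.
- **Event ordering**: a simplified order-constrained age-depth model for
  proxy cores (ordered calibration of tie-points + piecewise-linear
  interpolation) turns visually identified proxy drops into posterior
  calendar dates, and `temporal_difference()` gives the full posterior of
  the gap between a climatic event and a demographic change point.
- **A synthetic-data generator** producing calibration curves, date
  inventories from known growth parameters, clustered site maps, millet
  marks, and proxy cores with a known event date, so the whole pipeline
  is testable end-to-end without downloads.

## Worked example

Simulate a boom-and-bust population (growth 0.18 %/yr, decline
−0.14 %/yr, change point 5000 cal BP), push it through the whole
pipeline, and recover the generating parameters:

```r
library(c14demog)

curve <- make_calcurve(span = c(500, 9500), wiggle_amplitude = 20,
                       wiggle_period = 500, sigma = 15, seed = 1)
truth <- growth_params(r1 = 0.0018, r2 = -0.0014, c = 5000)
sim <- simulate_dataset(sim_config(growth = truth, n_dates = 500, seed = 2),
                        curve)

rec  <- filter_dates(sim$records)          # origin/marine/CRA-bracket rules
bins <- assign_bins(rec, eps_km = 1, h = 100)
spd  <- build_spd(rec, bins, curve, window = c(7000, 3000))
print(spd)
#> SPD over 7000 - 3000 cal BP; 300 bins; total mass 299.358

thin <- thin_bins(rec, bins, curve)        # one date per bin, mass >= 0.5
fit  <- fit_growth(thin, curve, chains = 2, iterations = 12000,
                   burnin = 3000, thin = 3, seed = 3)
summary(fit, level = 0.90)
#>   param    median      mean hpd_lower hpd_upper rhat  ess
#> 1    r1  1.65e-03  1.65e-03  1.33e-03  1.96e-03    1 1207
#> 2    r2 -1.01e-03 -1.01e-03 -1.24e-03 -7.81e-04    1 1232
#> 3     c  5.04e+03  5.04e+03  4.92e+03  5.16e+03    1  935
```

The 90% HPD intervals bracket the generating growth rate and change
point; the posterior median decline rate is attenuated toward zero, the
combined effect of the Normal(0, 0.0004) prior and of bin thinning in
dense periods (both discussed in the methods vignette,
`vignettes/radiocarbon-demography.Rmd`). `plot(fit)` draws the marginal
posteriors with shaded HPDs, `predictive_spd()` produces posterior
predictive SPD envelopes, and `mark_permutation_test()` /
`temporal_difference()` cover the subset-comparison and event-ordering
questions.

A thin command-line wrapper over the same functions is installed at
`inst/cli/c14demog.R` (subcommands `simulate`, `calibrate`, `spd`,
`permtest`, `fit`, `events`, `order`; every stochastic command requires
an explicit `--seed`, and each run writes a `manifest.json` with
settings, seed and input checksums).

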