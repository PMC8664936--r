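---
title: "Radiocarbon time-frequency data as a demographic proxy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiocarbon time-frequency data as a demographic proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(c14demog)
```

## The inferential problem

Radiocarbon date inventories are used as a population proxy on the
assumption that, within a region and period, the amount of datable
anthropogenic material scales with the number of people producing it.
Three sources of uncertainty stand between the raw data and a demographic
statement: the measurement error of each conventional radiocarbon age
(CRA), the non-linear and non-monotone calibration from `14C` years to
calendar years, and the very uneven intensity with which sites are
excavated and dated. `c14demog` treats all three explicitly: calibration
propagates both lab and curve error; spatio-temporal binning damps
inter-site differences in dating intensity; and the growth model is
fitted to the dates themselves (through latent calendar ages), never to
the summed curve, so SPD wiggles are not mistaken for data.

## Calibration

A calibration curve supplies the expected CRA `mu(t)` and its standard
deviation `sd(t)` at each calendar year `t` (cal BP, larger = older).
For a date with CRA `y` and lab error `s`, the calibrated probability
mass at `t` is proportional to the Gaussian density of `y` at `mu(t)`
with standard deviation `sqrt(s^2 + sd(t)^2)`; for marine samples a
reservoir offset ΔR is subtracted from `y` and its uncertainty added in
quadrature. Masses are normalized to sum to one.

Numerical choices:

* **Integer 1-year grid, per-year masses.** Densities are probability
  masses per calendar year, not densities per unit time, which makes
  within-bin normalization and SPD summation exact, with no quadrature
  weights. The curve is interpolated linearly in both mean and sigma
  between grid points (the curve files' own resolution is coarser than a
  year; linear interpolation is the field's standard practice).
* **Support padding.** Quantities that need "the whole calibrated
  density" (the thinning rule's window-mass fraction, bin normalization)
  are computed on the analysis window padded by 2000 years on each side
  and clipped to the curve span. A date whose window mass is anywhere
  near the 0.5 thinning threshold has negligible probability beyond that
  padding, so the truncation error is irrelevant while the cost stays
  bounded.
* **Empty densities.** A date incompatible with the analysis grid
  (all-zero density after underflow guarding in log space) is returned
  flagged rather than silently renormalized.
* **HPD intervals.** For discrete densities the highest-density region
  is built greedily by mass, which is provably the smallest set of grid
  points reaching the level; exact ties at the margin are kept together,
  so a symmetric density yields a symmetric region. For samples the
  single shortest interval containing the required fraction of draws is
  used.

## Binning and SPDs

Sites are clustered with DBSCAN on great-circle distances (spherical
Earth, radius 6371 km; at ε = 1 km projection error is negligible).
With `minPts = 1` — the default, and the configuration used throughout —
every site is a core point and DBSCAN reduces exactly to the connected
components of the ε-neighbourhood graph; the test suite exploits this by
checking the implementation against an independent graph-components
oracle. Within each spatial cluster, dates are grouped by
complete-linkage agglomerative clustering of their CRAs (uncalibrated,
matching the behaviour of the binning functions this procedure follows),
cut at `h = 100` years: two dates share a bin only if *every* pairwise
CRA difference in the bin is at most `h`.

Each bin contributes the *mean* of its members' calibrated densities, so
a fully-dated pit house and a once-dated one weigh the same; the SPD is
the sum of bin curves. For model fitting the record is thinned further:
the smallest-error date per bin is kept (ties broken by smallest CRA,
then input order — the rule must be deterministic for reproducibility),
and any survivor with less than half of its calibrated mass inside the
analysis window is dropped. The window-mass fraction is computed on the
date's full (padded) density *before* truncation, reading "cumulative
calibrated probability below 0.5 between the window bounds" as a
fraction of the whole density.

**A property worth knowing:** when per-cluster date density is high, the
100-year bins saturate — boom-period bins absorb several dates each —
and the thinned record is flatter than the underlying date density. The
effect is a feature of the binning procedure itself (it is what damps
over-dated contexts), but it attenuates the magnitude of fitted growth
rates when dates are many and sites few. The end-to-end recovery test
therefore uses a site-dense configuration in which binning deduplicates
rather than reshapes; analyses of strongly clustered inventories should
read the fitted rates as rates of the *binned* record.

## The mark-permutation test

The test asks whether the dates carrying a mark (say, association with
millet) are distributed over time differently from the rest. Group SPDs
are normalized to unit mass first — the millet subset is a few percent
of the sample, and the question posed is about *shape*, not abundance.
Marks are randomly reassigned without replacement `n_perm` times; the
envelope is the pointwise α/2 and 1−α/2 quantile band over permutations;
the global statistic is the summed out-of-envelope exceedance
`Σ_t max(0, obs_t − hi_t) + max(0, lo_t − obs_t)`, and the global
p-value is `(#{perm stat ≥ observed} + 1) / (n_perm + 1)` — the +1
correction keeps the p-value in `(0, 1]` and the test exact. (The raw
exceedance was chosen over a z-scored variant; with the permutation
reference distribution computed under the same envelope the choice
affects only the weighting of deviations across time, and raw exceedance
is the simpler, documented statistic.) With few records an exhaustive
mode enumerates all distinct relabellings and reports the exact
enumeration fraction instead. Binning can be switched on (regional
comparisons, where inter-site intensity differences matter) or off
(small marked subsets such as millet dates, where bin-averaging would
discard most of the signal).

## The growth model

The probability of sampling a date from calendar year `t` in the window
`[b, a]` (cal BP; `a = 7000`, `b = 3000` by default) follows a truncated
double-exponential: starting from weight 1 at `t = a`, the weight for
each successive (younger) year is multiplied by `(1 + r(t))`, where the
annual rate `r(t)` equals `r1` while `t > c` and `r2` once `t ≤ c`; the
weights are normalized to a proper PMF. The rate governing the step from
year `t` to `t − 1` is evaluated at `t` (the older endpoint), so growth
switches in the step *leaving* the change point and the PMF is
continuous at `c`; when `r1 = r2 = r` the definition collapses to the
familiar `(1 + r)^i / Σ (1 + r)^i`. A literal piecewise exponent
`(1 + r(t))^i` would jump discontinuously at `c`, contradicting
change-point semantics, which is why the cumulative-product reading is
used.

Priors: `r1, r2 ~ Normal(0, 0.0004)` — spanning the growth-rate
magnitudes typically estimated from date-frequency data — and
`c ~ TruncatedNormal(5000, 1000)` on `[3000, 7000]`, weakly informative
with slightly reduced mass at the window edges.

### MCMC

The default sampler is Metropolis-within-Gibbs over `(r1, r2, c)` plus
one latent calendar age per date. Latent ages carry the growth PMF as
prior and the Gaussian calibration likelihood; they are updated jointly
by a vectorized integer random walk, and the three parameters by
Gaussian random walks. `c` is sampled continuously and floored to the
year grid when the PMF is evaluated (its prior is continuous). All
proposal scales adapt toward 20–40% acceptance in batches of 50 during
burn-in only (diminishing Robbins–Monro steps), and are frozen
afterwards so the retained chain targets the exact posterior. Chain 1
starts from the canonical initialization (rates 0, `c` at the prior
mean, latent ages at each date's calibrated median); chains 2+ start
from prior draws, giving the overdispersion that makes convergence
diagnostics meaningful. Default settings follow the literature the model
comes from — 3 chains × 100,000 iterations, burn-in 10,000, thinning
6 — while tests and the acceptance script use shorter runs (typically
2 × 8,000–12,000, which at these data sizes already yield ESS near
1,000 and split-Rhat ≈ 1.00; the stated problem sizes are the package's
own choice of desk-scale defaults).

A second, grid-marginalized sampler integrates the latent ages out
(`method = "marginal"`): the likelihood of `(r1, r2, c)` is
`Σ_t p_t · N(y; mu(t), ·)` per date, evaluated with log-sum-exp
guards. It is slower per iteration but exact in the same posterior, and
the test suite uses agreement between the two samplers — plus a full
brute-force quadrature posterior on a 20-year toy window — as the
correctness oracle for the latent-age machinery.

Diagnostics are authored in the package: split-chain Gelman–Rubin
(halved chains, so within-chain trends register) with a 1.01 warning
threshold (modern convention), and effective sample size by Geyer's
initial-positive-sequence truncation of paired autocorrelations.
`coda`'s implementations serve as independent cross-checks in the test
suite only.

### Prior shrinkage

The Normal(0, 0.0004) rate prior is informative at the sample sizes this
model is used with: a true rate of 0.002/yr lies five prior standard
deviations from zero, and at n ≈ 500 dates the posterior median shrinks
toward zero by roughly a factor 0.85–0.9. This is correct Bayesian
behaviour, not a sampler artefact (the package verifies it by agreement
between both samplers and the shrunken maximum-likelihood estimate), but
it means coverage checks against fixed extreme truths are conservative,
and recovery simulations are best run with truths the prior actually
supports. Users analysing populations with strong growth may widen
`prior_spec(r_sd = ...)` accordingly.

### Predictive checks

`predictive_spd()` draws parameters (from the prior or from posterior
draws), samples calendar ages from the implied PMF, back-projects them
through the calibration curve with lab errors resampled from the
observed error list (the thinned record's errors, matching how the
observed SPD is built), calibrates and sums, and reports the pointwise
2.5%/97.5% envelope over (by default) 500 simulations.

## Age-depth models and event ordering

Proxy cores arrive as a depth/proxy series plus radiocarbon-dated
tie-points. The package's age-depth model is deliberately simple:
each tie-point's calendar age is drawn from its calibrated density
(marine tie-points through reservoir-corrected calibration against a
marine curve), joint draws violating stratigraphic order (deeper =
older) are rejected, and retained draws are interpolated
piecewise-linearly to every depth, extending the nearest segment's
accumulation rate beyond the outermost tie-points. Draw batches continue
until the requested ensemble size is reached; a rejection rate above
99.9% aborts with an error, since tie-points that incompatible need
re-examination, not silent forcing. Fully nonparametric accumulation
models (e.g. compound Poisson-Gamma) are intentionally out of scope —
the downstream computation needs only posterior event-date samples, so
ensembles produced by dedicated age-depth software can be supplied
directly to `event_dates()`.

Event depths are an *input* (the drops in a proxy series are identified
by inspection, as is standard); `event_dates()` reads the posterior age
at a depth, and `temporal_difference()` samples pairs independently from
two event posteriors and studies `A − B` in calendar years. The sign
convention is stated everywhere: on the cal BP scale smaller is more
recent, so "A occurred after B" means `A − B < 0`. Exact ties — possible
on integer-year grids — are counted as neither order and reported
separately rather than split arbitrarily.

## The synthetic-data generator

`make_calcurve()` builds identity-plus-sinusoid curves with optional
random-walk roughness and constant curve error: wiggly enough to
exercise multimodal calibration, degenerate enough (amplitude 0, walk 0)
to collapse calibration to a plain Gaussian for analytic tests.
`simulate_dataset()` draws calendar ages from a known growth PMF,
back-projects them to CRAs, and attaches sites placed in Gaussian
clusters a few hundred metres across (clusters alternate coastal/inland
labels; the default of 100 sites per 500 dates mirrors the
date-per-site density of regional inventories of this size), lab errors
uniform on 20–60 `14C` yr, and a Bernoulli millet mark at 6.6%.
`simulate_core()` lays down a linear age-depth relation, dates equally
spaced tie-points through the curve, and shapes the proxy as a smoothed
step dropping at the depth whose true age is the configured event date.

What the generator does *not* emulate — and what passing tests therefore
cannot certify about real data: taphonomic loss and research-intensity
gradients (the more-dates-more-people link is assumed, not tested),
plateau-heavy real calibration curves, non-constant reservoir offsets,
non-linear accumulation histories, and spatially realistic coastlines
(regions are cluster labels, as in the package's data model).

## Known limitations

* Fitted rates describe the binned-and-thinned record; under heavy bin
  saturation they understate the raw date-density rates (see above).
* The rate prior shrinks strong growth/decline estimates noticeably at
  typical sample sizes.
* The age-depth model assumes piecewise-linear accumulation between
  tie-points; hiatuses and rate excursions between tie-points are
  invisible to it.
* One change point only; no model comparison machinery (WAIC/LOO) and
  no hierarchical pooling across regions — regional fits are
  independent.
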