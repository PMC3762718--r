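---
title: "Dynamic occupancy models and the Wildlife Picture Index: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic occupancy models and the Wildlife Picture Index: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpiocc)
```

## The estimation problem

Camera-trap monitoring produces, per species, a ternary detection history:
for each sampling point and sampling period the species was photographed
(1), not photographed although the camera was active (0), or the point was
not sampled (NA). Naive occupancy — the fraction of sampled points with at
least one photo — is biased low by false negatives, and the bias varies
across species and years with detectability. The multi-season occupancy
model separates the ecological state from the observation process:

* **State, year 1.** $Z_{j1} \sim \mathrm{Bernoulli}(\psi_{j1})$ with
  $\mathrm{logit}(\psi_{j1}) = \beta^\top X_j$ for site covariates $X_j$
  (elevation, canopy height, distance to edge, ...).
* **State dynamics.** An occupied point stays occupied with apparent
  survival $\varphi_t$; an empty point is colonized with probability
  $\gamma_t$, giving $\psi_{t+1} = \psi_t\varphi_t + (1-\psi_t)\gamma_t$.
  The state is closed within a year; turnover happens only between years.
* **Observation.** In each of $K$ periods,
  $y_{jtk} \sim \mathrm{Bernoulli}(Z_{jt}\, p_t)$. Detection may be
  constant or year-specific; there are no within-year observation
  covariates (a deliberate restriction: point and year covariates only).

Days are collapsed to `n_periods = 15` blocks per year (roughly 7–8 days
each for a 30-day deployment). Remainder days are assigned one per block
to the earliest blocks — deterministic and order-preserving. A period is
NA only when *every* day in its block is NA: partial effort still carries
information, and the collapse never invents or destroys a detection, only
rescales the time unit of $p$.

## Two engines, one likelihood

`occudyn()` fits the model two ways behind one interface.

**Marginal maximum likelihood** sums the latent states out with a scaled
forward recursion over years (two-state HMM filter, vectorized across
sites; per-site likelihoods depend on the history only through the
detection and effort counts $d_{jt}, K_{jt}$). Optimization is BFGS on the
unconstrained scale (logit for probabilities) with `reltol = 1e-10`, a
data-driven heuristic start plus seeded random restarts (`n_starts = 5`
by default), standard errors from the inverse observed information, and
flags — not silent repairs — for non-convergence and boundary estimates
(|logit| > 8). This engine powers AIC selection over the six candidate
structures in `candidate_models()`; ties are broken toward fewer
parameters. Sparsely detected species (fewer than 15 site-detections in
every year) are restricted to the three structures without occupancy
covariates.

**MCMC** uses a self-contained Gibbs/Metropolis sampler: each latent
$Z_{jt}$ is drawn from its full conditional given its temporal neighbours,
the data and the parameters; $\varphi, \gamma, p$ get conjugate
Beta(1, 1)-prior updates from latent transition and detection counts; the
occupancy coefficients $\beta$ get a random-walk Metropolis step with
Normal(0, sd 10) priors, the proposal scale adapted only during burn-in
(so the post-burn-in chain is a fixed-kernel sampler). Defaults follow the
published configuration — 5 chains × 30,000 iterations, burn-in 20,000,
thinning 3 — and every parameter and derived annual occupancy is monitored
with the Gelman–Rubin statistic; any $\hat R > 1.1$ attaches a convergence
warning. All randomness is fixed by the seed in `mcmc_control()`.

Priors are vague and conjugate where possible, matching common published
hierarchical occupancy code; nothing in the data scales considered here is
prior-sensitive (the Beta(1, 1) adds one pseudo-count against hundreds of
latent trials).

## Derived annual occupancy: two flavours

Each retained draw yields annual occupancy two ways:

* **finite-sample** — the mean of the sampled latent states across the
  monitored points, $\frac1n\sum_j Z_{jt}$. This is the estimand "what
  fraction of *these* points was occupied", and it is the default input to
  the WPI and λ.
* **expected** — the parametric recursion from the mean of
  $\psi_{j1}$ under that draw's $\beta, \varphi, \gamma$ (for covariate
  models the across-site mean summarizes the site-varying $\psi$).

The distinction matters for interpretation: the finite-sample index tracks
what actually happened at the 60 points, including the realization noise
of the occupancy process itself. On a 60-point design the realized
community trajectory of a perfectly stationary community still wanders a
few percent per year, and a well-calibrated posterior follows that
wandering rather than the design expectation. The truth-recovery tests
therefore compare estimates against the *realized* index computed from the
simulated latent states, and check absence of *systematic* drift against
the design value across replicates.

## Community indicators

**WPI.** At each draw $m$ and year $t$, the index is the geometric mean
over the species set of occupancy relative to the same draw's baseline
year: $\mathrm{WPI}_{t,m} = (\prod_i \psi_{i,t,m}/\psi_{i,1,m})^{1/S}$.
Species are fitted independently, so the $m$-th retained draw of each
species is paired — exactly what computing the index "at each model
iteration" across separate fits implies. The baseline year is 1 in every
draw by construction. Zero baseline draws are floored at $10^{-6}$ and the
species flagged. The per-year point estimate is the *smaller* of the
median and the half-sample mode (posteriors of ratios are right-skewed;
taking the lower of the two central-tendency estimates is deliberately
conservative), with a 95% HPDI. `group_wpi()` disaggregates by hunting
status, guild (large vs small herbivores split at 20 kg body mass), or
IUCN status (least concern vs species of conservation interest).

**λ classification.** For every ordered year pair, the posterior of
$\lambda = \psi(t+n)/\psi(t)$ is summarized by its 95% HPDI: *decline* if
the upper bound is below 1, *increase* if the lower bound is above 1,
otherwise *no change*. The same rule applies to WPI ratios.

**HPDI and mode.** The HPDI is the shortest contiguous window of sorted
draws containing $\lceil 0.95\,n\rceil$ of them (cross-checked in the
tests against an exhaustive window scan). The mode is the deterministic
half-sample mode — recursively keep the shortest half of the sorted sample
— chosen over kernel-density modes to avoid a bandwidth parameter; with
fewer than 100 draws the index point estimate falls back to the median.

**Goodness of fit.** The chi-square discrepancy between annual aggregated
detection counts and their expectation is
$\sum_t (O_t - E_t)^2/(E_t + 0.5)$; the 0.5 stabilizer guards the rare
species whose expected counts approach zero. Per retained draw, $E_t$ is
computed *conditional on that draw's latent states* ($E_t = p_t \sum_j
K_{jt} Z_{jt}$ — the per-iteration discrepancy of the standard hierarchical
idiom), a replicate dataset is generated from the same draw with the
observed effort pattern (effort is design, not part of the stochastic
model), and the Bayesian p-value is the fraction of draws whose replicated
discrepancy exceeds the observed one. The replicate is compared against
the same $E_t$ as the data; the alternative reading (a freshly drawn
expectation) is noted but not implemented. Values very near 0 or 1 signal
misfit. DIC is computed on the marginal (latent-states-summed) deviance,
$p_D = \bar D - D(\bar\theta)$ at the posterior mean of the parameters;
AIC ranks the ML fits and DIC the Bayesian refits, side by side.

**Richness.** Relative richness treats the species-by-point matrix of a
year as a detection history in which the sampling unit is a *species* and
the replicates are points: $\psi_S(t)$ is the proportion of the regional
pool present, scaled by the pool size (40 in the motivating system) to a
species count. Detection is modeled with standardized $\log_{10}$ body
mass (mass spans two orders of magnitude, so the log scale is the
ecologically sensible continuous covariate), trophic guild and an additive
year effect. Pool members never detected enter as all-zero rows — they are
informative under the model. Confidence intervals come from a
nonparametric bootstrap over sampling points (the replicate unit), 500
iterations by default, refitting from the full-data estimates; both the
bootstrap SE and the 95% percentile interval are reported since either may
be wanted.

## The synthetic-data generator

`simulate_community()` draws communities from *exactly* the model above —
no extra structure — so every downstream stage can be tested against known
truth. What it emulates: the 60-point × 5-season × 15-period design; a
13-species assemblage spanning the detectability range of a neotropical
terrestrial mammal community (common small herbivores with $p \approx
0.35$–0.45 per period down to rare cats at $p \approx 0.12$); an
elevation gradient (30–3000 m) with correlated canopy height and edge
distance; camera-failure missingness shared across species (a dead camera
records nothing for anyone), 3% per cell by default — matching the few
percent of scheduled effort a real deployment loses — with an optional
tail-truncation mode (camera dies, all later periods NA). The `stable`
preset derives each species' colonization from stationarity,
$\gamma = \psi(1-\varphi)/(1-\psi)$, so expected occupancy is constant and
the true community index is 1 every year; `hunted_decline` lowers the
hunted small herbivores' survival to $\varphi = 0.78$ with $\gamma = 0.02$,
roughly halving their occupancy over three transitions while the hunted
large herbivore stays stable — so the hunted *group* declines through its
small-herbivore members.

What it does **not** emulate: spatial autocorrelation between points,
animal movement or home ranges, within-year covariates on detection, and
observation heterogeneity beyond the model (misidentification, clustered
failures). Passing tests therefore demonstrate correctness of the
estimators *under the model's own assumptions* — parameter recovery,
calibration, selection — not robustness to the violations real data can
carry.

## Numerical choices and degenerate inputs

* Forward recursion renormalizes per year and accumulates the
  log-constant, so long series cannot underflow; all-NA site-years
  contribute exactly zero log-likelihood.
* `within_year_prob` returns 1 for an all-NA year (vacuous product) and
  0 for a detection at an "unoccupied" state — impossible events have
  probability zero, not an error.
* Covariates are standardized (mean 0, SD 1 over the analysed points) so
  logit coefficients are comparable; categorical covariates are one-hot
  expanded against the alphabetically first level; zero-variance columns
  are rejected by name.
* Boundary ML estimates (e.g. $p \to 1$ under saturated data) are
  reported with a flag rather than clamped.
* Degenerate posteriors (zero-width HPDIs) are legal: a constant draw
  vector yields the interval $[c, c]$ and classification proceeds.

## Problem sizes used by tests and the acceptance script

The statistical checks run at the study's design scale (60–200 sites, 5
years, 15 periods) with reduced sampler settings — typically 2–3 chains of
1,500–2,500 iterations — which the convergence diagnostics show are ample
for these models ($\hat R \le 1.01$); the paper-scale 5 × 30,000
configuration remains the default for real analyses. Recovery and
selection use 20 replicates, predictive-check calibration 50, community
truth-recovery 10; richness bootstraps are shortened in tests. These sizes
are stated here so results are interpreted at the Monte-Carlo precision
they carry.

## Known limitations

* Species are fitted independently; the WPI pairing of draws across
  species assumes (correctly, here) independent posteriors, and there is
  no shared-information community model.
* The finite-sample index is conditional on the monitored points;
  extrapolation to a region needs the expected-ψ flavour and a design
  argument.
* No N-mixture abundance models, no spatial random effects, no GAM
  smoothing of trajectories, and no GIS derivation of covariates — site
  covariates are consumed as a table.
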