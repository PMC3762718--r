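# wpiocc

Occupancy-based monitoring of terrestrial vertebrate communities from
camera-trap data: multi-season (dynamic) occupancy models with imperfect
detection, posterior-derived community indicators — the Wildlife Picture
Index (WPI), λ-ratio change classification, detection-corrected species
richness — and a synthetic-community generator with known truth for
calibration and power studies.

The package is aimed at ecologists running standardized camera-trap
monitoring programs (tens of points resampled annually) who want trend
statements per species and for the community that are corrected for the
detection process, rather than raw photo counts or naive occupancy.

## The model

For species *i* at sampling point *j*, presence in the first season is a
latent Bernoulli state with a logit-linear covariate link:

    Z_ij1 ~ Bernoulli(psi_ij1),      logit(psi_ij1) = beta' X_j

Between seasons an occupied point stays occupied with apparent survival
φ (local extinction 1−φ) and an empty point is colonized with probability
γ, giving the recursion ψ_{t+1} = ψ_t φ_t + (1−ψ_t) γ_t. Within a season
the state is closed, and each of the (by default 15) sampling periods
yields an observation

    y_ijtk ~ Bernoulli(Z_ijt * p_it)

with detection probability *p* (constant or year-specific). The marginal
likelihood sums the latent states out by forward recursion, which powers
maximum-likelihood fits and AIC selection across the six candidate
structures ψ(·)/ψ(cov) × γ(year)/γ(·) × φ(year)/φ(·) × p(·)/p(year). A
self-contained Gibbs/Metropolis sampler (conjugate Beta updates for φ, γ,
p given the latent states; random-walk Metropolis for β) provides
posteriors, convergence is monitored with the Gelman–Rubin statistic, and
fit is checked with a chi-square Bayesian posterior predictive check on
annual detection frequencies.

Community indicators are derived per posterior draw: the WPI is the
geometric mean across species of occupancy relative to the baseline year
(1 = no community change), change between years *t* and *t+n* is the ratio
λ = ψ(t+n)/ψ(t) classified by whether its 95% highest-posterior-density
interval lies below, above, or across 1, and relative species richness is
a dynamic occupancy model over the species-by-point detection matrix,
scaled by the regional species pool.

## Worked example

Simulate one declining species at 60 points over 5 seasons (year-1
occupancy 0.6, survival 0.8, colonization 0.1, per-period detection 0.15 —
well below the stationary occupancy γ/(γ+1−φ) = 0.33, so occupancy falls),
fit it by MCMC, and classify the change:

```r
library(wpiocc)
sim <- simulate_species(species_params(qlogis(0.6), phi = 0.8, gamma = 0.1, p = 0.15),
                        n_sites = 60, n_years = 5, n_periods = 15, seed = 11)
fit <- occudyn(sim$data, gamma = "constant", phi = "constant",
               engine = "mcmc", mcmc = mcmc_control(3, 4000, 1500, 2, seed = 1))
fit
#> Multi-season occupancy model, structure psi(.) gamma(.) phi(.) p(.)
#>   engine: MCMC (3 chains x 4000 iterations, burn-in 1500, thin 2)
#>   max R-hat: 1.001
#>   annual occupancy: 0.800, 0.700, 0.633, 0.500, 0.433
#>   naive occupancy:  0.700, 0.683, 0.567, 0.450, 0.383

round(summary(fit)$table, 3)
#>                 median hpdi_lo hpdi_hi  rhat
#> psi_(Intercept)  1.346   0.693   2.185 1.000
#> phi              0.813   0.738   0.874 1.001
#> gamma            0.095   0.030   0.179 1.001
#> p                0.145   0.131   0.159 1.000

lam <- lambda_matrix(fit)
lam[lam$from == 1, ]
#>   from to lambda hpdi_lo hpdi_hi   trend
#> 1    1  2  0.894   0.824   0.957 decline
#> 2    1  3  0.796   0.729   0.872 decline
#> 3    1  4  0.633   0.569   0.702 decline
#> 4    1  5  0.542   0.479   0.622 decline

bppc(fit, seed = 1)
#> Bayesian posterior predictive check (chi-square)
#>   Bayesian p-value: 0.468 over 3750 draws
```

Modeled annual occupancy sits above the naive values — the correction for
false negatives at p = 0.15 per period — the posterior recovers the
generating parameters, the λ ratios classify the decline from year 1
onward, and the posterior predictive check shows no lack of fit.

For a whole community, `simulate_community(community_scenario("stable"))`
(or `"hunted_decline"`) generates 13 species with known truth;
`occupancy_posterior()` stacks their fits, `wpi_series()` /
`group_wpi()` / `lambda_matrix()` derive the indicators, and
`richness_fit()` estimates detection-corrected richness. `run_pipeline()`
drives the whole chain from a YAML config (see
`inst/scripts/run-pipeline.R` for a shell entry point).

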