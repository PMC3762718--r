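test_that("site covariate simulation is reproducible and respects its knobs", {
  a <- simulate_site_covariates(60, seed = 4)
  b <- simulate_site_covariates(60, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 60L)
  expect_true(all(a$elevation >= 30 & a$elevation <= 3000))
  # uncorrelated configuration yields near-zero sample correlation
  c0 <- simulate_site_covariates(200, seed = 7, canopy_cor = 0, edge_cor = 0)
  expect_lt(abs(cor(c0$elevation, c0$canopy_height)), 0.3)
  expect_lt(abs(cor(c0$elevation, c0$edge_distance)), 0.3)
  # strong correlation configuration is visible in the sample
  c1 <- simulate_site_covariates(200, seed = 7, canopy_cor = 0.9)
  expect_gt(cor(c1$elevation, c1$canopy_height), 0.6)
})

test_that("species simulation honours perfect detection and frozen dynamics", {
  pars <- species_params(qlogis(0.6), phi = 1, gamma = 0, p = 1)
  sim <- simulate_species(pars, n_sites = 40, n_years = 4, n_periods = 5, seed = 2)
  # frozen dynamics: Z constant across years
  expect_true(all(sim$Z == sim$Z[, 1]))
  # perfect detection: every occupied site-year detected in every period
  for (t in 1:4) {
    expect_equal(unname(sim$data$y[[t]][, 1]), sim$Z[, t])
    expect_true(all(sim$data$y[[t]][sim$Z[, t] == 1, ] == 1))
    expect_true(all(sim$data$y[[t]][sim$Z[, t] == 0, ] == 0))
  }
  # detections only at occupied sites, in general
  s2 <- simulate_species(species_params(0, 0.8, 0.2, 0.5),
                         n_sites = 100, n_years = 3, n_periods = 10, seed = 3)
  for (t in 1:3)
    expect_true(all(s2$data$y[[t]][s2$Z[, t] == 0, ] == 0))
})

test_that("year-1 occupancy matches its Bernoulli expectation at large n", {
  sim <- simulate_species(species_params(0, 0.8, 0.1, 0.4),
                          n_sites = 10000, n_years = 1, n_periods = 1, seed = 5)
  # logit-intercept 0 -> psi = 0.5; binomial 3 SE = 3 * sqrt(0.25/10000)
  expect_lt(abs(mean(sim$Z[, 1]) - 0.5), 0.015)
})

test_that("occupancy trajectories follow the survival/colonization recursion", {
  psi1 <- 0.6; phi <- c(0.9, 0.7, 0.8); gamma <- c(0.1, 0.3, 0.05)
  sim <- simulate_species(species_params(qlogis(psi1), phi, gamma, p = 0.5),
                          n_sites = 5000, n_years = 4, n_periods = 3, seed = 8)
  expected <- Reduce(function(ps, t) c(ps, occupancy_recursion(ps[t], phi[t], gamma[t])),
                     1:3, accumulate = FALSE, init = psi1)
  emp <- colMeans(sim$Z)
  for (t in 1:4) {
    se <- sqrt(expected[t] * (1 - expected[t]) / 5000)
    expect_lt(abs(emp[t] - expected[t]), 3 * se + 1e-9)
  }
  # conditional detection frequency matches p among occupied site-years
  occ <- sim$Z == 1
  freq <- mean(unlist(lapply(1:4, function(t) sim$data$y[[t]][occ[, t], ])))
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / sum(occ) / 3))
})

test_that("missingness hits the target rate and never invents detections", {
  m <- matrix(rbinom(10000, 1, 0.3), 100)
  expect_identical(apply_missingness(m, 0), m)
  out <- apply_missingness(m, 0.2, seed = 6)
  expect_lt(abs(mean(is.na(out)) - 0.2), 0.012)   # binomial 3 SE
  expect_true(all(out[!is.na(out)] == m[!is.na(out)]))
  # pooling the degraded matrix with the original restores it
  expect_equal(strip_attrs(pool_species(list(out, m))), strip_attrs(m))
  # tail mode produces contiguous trailing NA runs only
  tl <- apply_missingness(m, 0.5, seed = 6, mode = "tail")
  runs <- apply(tl, 1, function(r) {
    nas <- which(is.na(r))
    !length(nas) || identical(nas, seq(min(nas), ncol(m)))
  })
  expect_true(all(runs))
})

test_that("community presets encode their intended dynamics", {
  sc <- simulate_community(community_scenario("stable", seed = 10))
  expect_length(sc$species, 13L)
  expect_equal(unname(sc$truth$wpi_true), rep(1, 5), tolerance = 1e-12)
  # same seed reproduces the bundle exactly
  sc2 <- simulate_community(community_scenario("stable", seed = 10))
  expect_identical(sc$species$paca$data$y, sc2$species$paca$data$y)
  # decline preset halves flagged species' occupancy by year 4
  dc <- simulate_community(community_scenario("hunted_decline", seed = 10))
  flagged <- dc$attributes$species_id[dc$attributes$hunted &
                                        dc$attributes$guild == "small_herbivore"]
  for (sp in flagged) {
    tr <- dc$truth$psi_expected[sp, ]
    expect_lte(tr[4] / tr[1], 0.6)
  }
  # unflagged species remain stationary
  stable_sp <- setdiff(rownames(dc$truth$psi_expected), flagged)
  expect_equal(dc$truth$psi_expected[stable_sp, 5],
               dc$truth$psi_expected[stable_sp, 1], tolerance = 1e-9)
  # shared missingness pattern: NA cells coincide across species
  na1 <- is.na(sc$species$paca$data$y[[1]])
  na2 <- is.na(sc$species$jaguar$data$y[[1]])
  expect_identical(na1, na2)
})

test_that("scenario configs round-trip through YAML", {
  pth <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: hunted_decline", "n_sites: 20", "n_years: 3",
               "miss_prob: 0.1", "seed: 99"), pth)
  sc <- scenario_from_config(pth)
  expect_s3_class(sc, "community_scenario")
  expect_equal(sc$n_sites, 20L)
  expect_equal(sc$preset, "hunted_decline")
  expect_equal(sc$seed, 99L)
})
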