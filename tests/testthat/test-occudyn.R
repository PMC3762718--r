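# One moderately large simulated dataset shared across fitting tests.
recovery_sim <- local({
  simulate_species(species_params(qlogis(0.6), 0.8, 0.1, 0.4),
                   n_sites = 200, n_years = 5, n_periods = 15, seed = 42)
})

test_that("maximum likelihood recovers generating parameters", {
  fit <- occudyn(recovery_sim$data, gamma = "constant", phi = "constant",
                 p = "constant")
  est <- plogis(coef(fit))
  expect_lt(abs(est[["psi_(Intercept)"]] - 0.6), 0.08)
  expect_lt(abs(est[["phi"]] - 0.8), 0.08)
  expect_lt(abs(est[["gamma"]] - 0.1), 0.08)
  expect_lt(abs(est[["p"]] - 0.4), 0.08)
  expect_true(fit$convergence)
  expect_false(fit$boundary)
  expect_equal(fit$AIC, 2 * 4 - 2 * fit$logLik)
  # standard errors from the observed information are finite and positive
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
})

test_that("saturated data is fit exactly and flagged at the boundary", {
  y <- lapply(1:2, function(t) matrix(1L, 10, 4))
  dat <- occu_data(y)
  fit <- suppressWarnings(occudyn(dat, gamma = "constant", phi = "constant"))
  # with truth psi1 = p = 1 the log-likelihood at the optimum is 0
  expect_lt(abs(fit$logLik), 1e-3)
  expect_true(fit$boundary)
})

test_that("detection-corrected occupancy exceeds naive occupancy under low p", {
  ests <- naives <- numeric(20)
  for (r in 1:20) {
    sim <- simulate_species(species_params(qlogis(0.5), 0.8, 0.15, 0.3),
                            n_sites = 60, n_years = 3, n_periods = 5,
                            seed = 300 + r)
    fit <- suppressWarnings(occudyn(sim$data, gamma = "constant",
                                    phi = "constant", n_starts = 2))
    ests[r] <- plogis(coef(fit)[["psi_(Intercept)"]])
    naives[r] <- naive_occupancy(sim$data$y[[1]])
  }
  expect_gt(mean(ests), mean(naives))
})

test_that("the MCMC engine is deterministic and agrees with ML when identified", {
  ctl <- mcmc_control(n_chains = 2, n_iter = 1500, burn_in = 700, thin = 2,
                      seed = 9)
  m1 <- occudyn(recovery_sim$data, gamma = "constant", phi = "constant",
                engine = "mcmc", mcmc = ctl)
  m2 <- occudyn(recovery_sim$data, gamma = "constant", phi = "constant",
                engine = "mcmc", mcmc = ctl)
  expect_identical(m1$draws, m2$draws)
  expect_equal(nrow(m1$draws), 2 * ((1500 - 700) %/% 2))
  expect_true(all(m1$psi_fs >= 0 & m1$psi_fs <= 1))
  # ML and posterior agree within 2 posterior SDs on identified data
  ml <- occudyn(recovery_sim$data, gamma = "constant", phi = "constant")
  post_med <- apply(m1$draws, 2, median)
  post_sd <- apply(m1$draws, 2, sd)
  mle <- c(coef(ml)[1], plogis(coef(ml)[-1]))
  expect_true(all(abs(post_med - mle) < 2 * post_sd))
})

test_that("forced-detection data pushes posterior occupancy above 0.95", {
  y <- lapply(1:3, function(t) matrix(1L, 15, 5))
  dat <- occu_data(y)
  fit <- suppressWarnings(occudyn(dat, gamma = "constant", phi = "constant",
                engine = "mcmc",
                mcmc = mcmc_control(2, 1200, 500, 2, seed = 3)))
  expect_true(all(apply(fit$psi_fs, 2, quantile, 0.05) > 0.95))
})

test_that("candidate set and fitting surface cover the published structures", {
  cands <- candidate_models()
  expect_length(cands, 6L)
  expect_length(candidate_models(null_only = TRUE), 3L)
  covs <- standardize_covariates(simulate_site_covariates(60, seed = 1))
  sim <- simulate_species(species_params(qlogis(0.5), 0.85, 0.1, 0.4),
                          covariates = covs, n_years = 3, n_periods = 8,
                          seed = 12)
  fits <- suppressWarnings(fit_candidates(sim$data, n_starts = 2))
  expect_named(fits, names(cands))
  ks <- vapply(fits, function(f) f$n_params, 0L)
  # psi(.) g(yr) phi(yr) p(.): 1 + 2 + 2 + 1 parameters at 3 years
  expect_equal(unname(ks[["psi(.)gam(yr)phi(yr)p(.)"]]), 6L)
  expect_equal(unname(ks[["psi(Ele+Can)gam(yr)phi(yr)p(.)"]]), 8L)
})

test_that("fit methods expose the standard modelling interface", {
  fit <- occudyn(recovery_sim$data, gamma = "constant", phi = "constant")
  expect_s3_class(fit, "occudyn")
  expect_equal(AIC(fit), fit$AIC)
  expect_output(print(fit), "Multi-season occupancy model")
  expect_output(print(summary(fit)), "Parameters")
  psi <- predict(fit, type = "psi")
  expect_equal(dim(psi), c(200L, 5L))
  expect_equal(colMeans(psi), fit$psi_annual)
  reps <- simulate(fit, nsim = 2, seed = 7)
  expect_length(reps, 2L)
  expect_s3_class(reps[[1]], "occu_data")
  # replicates reuse the observed missingness pattern
  expect_identical(is.na(reps[[1]]$y[[1]]), is.na(fit$data$y[[1]]))
  r <- residuals(fit)
  expect_equal(dim(r), c(200L, 5L))
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.2)
  pth <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pth); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pth))
})

test_that("posterior draws export and re-import exactly", {
  fit <- occudyn(recovery_sim$data, gamma = "constant", phi = "constant",
                 engine = "mcmc",
                 mcmc = mcmc_control(2, 800, 300, 2, seed = 4))
  pth <- withr::local_tempfile(fileext = ".csv")
  export_posterior(fit, pth)
  back <- read_posterior_draws(pth)
  expect_equal(unname(back[, "phi"]), unname(fit$draws[, "phi"]))
  expect_equal(unname(back[, "psi_fs_3"]), unname(fit$psi_fs[, 3]))
})
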