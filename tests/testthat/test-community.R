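test_that("HPDI is the shortest window and matches an exhaustive scan", {
  expect_equal(hpdi(1:100), c(1, 95) + c(0, 0))
  expect_equal(diff(hpdi(1:100)), 94)
  expect_equal(hpdi(rep(3.7, 50)), c(3.7, 3.7))
  set.seed(31)
  draws <- rbeta(1e5, 2, 5)
  expect_equal(hpdi(draws), hpdi_scan(draws))
  draws2 <- rexp(5000)
  expect_equal(hpdi(draws2, 0.8), hpdi_scan(draws2, 0.8))
  expect_error(hpdi(1:10), "at least 20")
})

test_that("half-sample mode targets the density peak deterministically", {
  set.seed(32)
  x <- rnorm(1e5)
  expect_lt(abs(posterior_mode(x) - median(x)), 0.05)
  expect_equal(posterior_mode(rep(2.5, 200)), 2.5)
  # right-skewed: mode below the median
  y <- rexp(1e5)
  expect_lt(posterior_mode(y), median(y))
  expect_identical(posterior_mode(y), posterior_mode(y))
  expect_error(posterior_mode(1:50), "at least 100")
})

# small hand-built posterior: 3 species x 3 years x 40 draws
toy_occ <- function() {
  set.seed(33)
  draws <- array(NA_real_, c(3, 3, 40))
  draws[1, , ] <- rbind(0.4, 0.4, 0.4)          # constant
  draws[2, , ] <- rbind(0.4, 0.2, 0.1)          # halving
  draws[3, , ] <- matrix(runif(120, 0.2, 0.8), 3)
  occupancy_posterior(list(a = t(draws[1, , ]), b = t(draws[2, , ]),
                           c = t(draws[3, , ])),
                      species_attributes = data.frame(
                        species_id = c("a", "b", "c"),
                        guild = c("omnivore", "small_herbivore", "carnivore"),
                        hunted = c(FALSE, TRUE, FALSE),
                        iucn_status = c("LC", "LC", "EN")))
}

test_that("relative occupancy rescales to the baseline year", {
  occ <- toy_occ()
  rel <- relative_occupancy(occ)
  expect_true(all(rel$psi[, 1, ] == 1))
  expect_equal(rel$psi[2, , 1], c(1, 0.5, 0.25))
  # idempotent: rescaling a relative posterior changes nothing
  rel2 <- relative_occupancy(rel)
  expect_equal(rel2$psi, rel$psi)
})

test_that("WPI is a baseline-1 geometric mean with the stated point rule", {
  occ <- toy_occ()
  w <- wpi_series(occ)
  expect_true(all(w$draws[1, ] == 1))
  # two species at relative occupancy 0.5 and 2.0 cancel geometrically
  flat <- occupancy_posterior(list(
    u = matrix(c(0.4, 0.2), 30, 2, byrow = TRUE),
    v = matrix(c(0.3, 0.6), 30, 2, byrow = TRUE)))
  expect_equal(unname(wpi_series(flat)$draws[2, ]), rep(1, 30))
  # three species all at one quarter of baseline
  q <- occupancy_posterior(list(
    x = matrix(c(0.8, 0.2), 30, 2, byrow = TRUE),
    y = matrix(c(0.4, 0.1), 30, 2, byrow = TRUE),
    z = matrix(c(0.2, 0.05), 30, 2, byrow = TRUE)))
  expect_equal(unname(wpi_series(q)$draws[2, ]), rep(0.25, 30))
  # geometric mean never exceeds the arithmetic mean of relative occupancies
  rel <- relative_occupancy(occ)$psi
  am <- apply(rel, c(2, 3), mean)
  expect_true(all(w$draws <= am + 1e-12))
  # permutation invariance
  w2 <- wpi_series(occ, subset = c("c", "a", "b"))
  expect_equal(sort(unname(w2$draws[3, ])), sort(unname(w$draws[3, ])))
})

test_that("group WPI partitions the community", {
  occ <- toy_occ()
  gw <- group_wpi(occ, "hunted")
  expect_named(gw, c("hunted", "not_hunted"), ignore.order = TRUE)
  expect_setequal(unlist(lapply(gw, `[[`, "species")), occ$species)
  # single-species group: the index is that species' relative occupancy
  expect_equal(unname(gw$hunted$draws[2, ]), rep(0.5, 40))
  # grouping by a constant attribute reproduces the community index
  occ$attributes$iucn_status <- "LC"
  g1 <- group_wpi(occ, "iucn")
  expect_length(g1, 1L)
  expect_equal(g1[[1]]$draws, wpi_series(occ)$draws)
  expect_error(group_wpi(occ, "elevation"), "arg")
})

test_that("lambda ratios are classified by the HPDI-against-1 rule", {
  # degenerate draws: ratio exactly 0.8 -> decline
  d <- matrix(c(1, 0.8), nrow = 2, ncol = 50)
  d[1, ] <- 1
  lam <- lambda_matrix(d)
  expect_equal(lam$trend[lam$from == 1 & lam$to == 2], "decline")
  # wide interval spanning 1 -> no_change; interval above 1 -> increase
  set.seed(34)
  up <- rbind(rep(1, 200), runif(200, 1.05, 1.4))
  expect_equal(lambda_matrix(up)$trend, "increase")
  mid <- rbind(rep(1, 200), runif(200, 0.8, 1.2))
  expect_equal(lambda_matrix(mid)$trend, "no_change")
  # all ordered year pairs are present
  three <- matrix(runif(3 * 100, 0.2, 0.9), 3)
  lm3 <- lambda_matrix(three)
  expect_equal(nrow(lm3), 3L)
  expect_equal(lm3[, c("from", "to")],
               data.frame(from = c(1, 1, 2), to = c(2, 3, 3)))
})

test_that("species lambda equals the lambda of its own one-species index", {
  occ <- toy_occ()
  lam_sp <- lambda_matrix(occ, species = "b")
  lam_wpi <- lambda_matrix(wpi_series(occ, subset = "b"))
  expect_equal(lam_sp$lambda, lam_wpi$lambda, tolerance = 1e-12)
  expect_equal(lam_sp$trend, lam_wpi$trend)
})

test_that("richness scaling and the perfect-detection community are exact", {
  expect_equal(scale_richness(0.45, 40), 18)
  # 20 of 40 pool species present, detected at every point every year
  n_pool <- 40; n_sites <- 25; n_years <- 3
  present <- rep(c(1L, 0L), each = 20)
  y <- lapply(1:n_years, function(t) {
    m <- matrix(rep(present, n_sites), n_pool, n_sites)
    rownames(m) <- sprintf("sp%02d", 1:n_pool)
    m
  })
  at <- data.frame(species_id = sprintf("sp%02d", 1:n_pool),
                   body_mass_kg = exp(runif(n_pool, 0, 5)),
                   guild = rep(c("carnivore", "omnivore", "small_herbivore",
                                 "large_herbivore"), 10))
  rich <- suppressWarnings(richness_fit(y, at, pool_size = 40, n_boot = 0))
  expect_equal(rich$estimates$richness, rep(20, n_years), tolerance = 0.05)
  expect_equal(rich$estimates$naive, rep(20, n_years))
  expect_true(all(rich$estimates$richness <= 40))
  expect_error(richness_fit(y, at[-1, ], pool_size = 40), "no attributes")
  expect_error(richness_fit(y, at, pool_size = 10), "smaller")
})

test_that("richness confidence intervals tighten with more sampling points", {
  set.seed(36)
  n_pool <- 30
  at <- data.frame(species_id = sprintf("sp%02d", 1:n_pool),
                   body_mass_kg = exp(runif(n_pool, 0, 5)),
                   guild = rep(c("carnivore", "omnivore", "small_herbivore"), 10))
  gen <- function(n_sites) {
    z <- rbinom(n_pool, 1, 0.5)
    lapply(1:2, function(t) {
      m <- matrix(rbinom(n_pool * n_sites, 1, rep(z * 0.4, n_sites)),
                  n_pool, n_sites)
      rownames(m) <- at$species_id
      m
    })
  }
  r_small <- suppressWarnings(richness_fit(gen(20), at, n_pool, n_boot = 60,
                                           seed = 5, n_starts = 1))
  r_large <- suppressWarnings(richness_fit(gen(80), at, n_pool, n_boot = 60,
                                           seed = 5, n_starts = 1))
  w_small <- median(r_small$estimates$ci_hi - r_small$estimates$ci_lo)
  w_large <- median(r_large$estimates$ci_hi - r_large$estimates$ci_lo)
  expect_lt(w_large, w_small)
})
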