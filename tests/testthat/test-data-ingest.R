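make_toy_tables <- function() {
  events <- data.frame(
    species_id = c("paca", "paca", "paca", "agouti"),
    site_id = c("A", "A", "B", "A"),
    date = as.Date(c("2010-01-02", "2010-01-02", "2010-01-04", "2010-01-03")),
    stringsAsFactors = FALSE)
  deployments <- data.frame(
    site_id = c("A", "B"),
    start_date = as.Date(c("2010-01-01", "2010-01-02")),
    end_date = as.Date(c("2010-01-03", "2010-01-04")),
    stringsAsFactors = FALSE)
  list(events = events, deployments = deployments)
}

test_that("daily matrix construction marks detections, zeros and NA correctly", {
  tt <- make_toy_tables()
  m <- build_daily_matrix(tt$events, tt$deployments, "paca", 2010)
  # window spans Jan 1-4; A active 1-3, B active 2-4
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(unname(m["A", ]), c(0L, 1L, 0L, NA))   # duplicates collapse to 1
  expect_equal(unname(m["B", ]), c(NA, 0L, 0L, 1L))
  expect_identical(attr(m, "species_id"), "paca")
  # a species with no events at a site gives zeros on active days only
  m2 <- build_daily_matrix(tt$events, tt$deployments, "agouti", 2010)
  expect_equal(unname(m2["B", ]), c(NA, 0L, 0L, 0L))
})

test_that("events outside deployments or at unknown sites are rejected", {
  tt <- make_toy_tables()
  bad <- rbind(tt$events, data.frame(species_id = "paca", site_id = "A",
                                     date = as.Date("2010-01-04")))
  expect_error(build_daily_matrix(bad, tt$deployments, "paca", 2010),
               "not active")
  bad2 <- rbind(tt$events, data.frame(species_id = "paca", site_id = "Z",
                                      date = as.Date("2010-01-02")))
  expect_error(build_daily_matrix(bad2, tt$deployments, "paca", 2010),
               "unknown site")
  ov <- rbind(tt$deployments, data.frame(site_id = "A",
                                         start_date = as.Date("2010-01-03"),
                                         end_date = as.Date("2010-01-05")))
  expect_error(build_daily_matrix(tt$events, ov, "paca", 2010), "overlap")
})

test_that("period collapse applies the any-detection / all-NA rules", {
  m <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(unname(collapse_to_periods(m, 2)[1, ]), c(1L, 0L))
  m2 <- matrix(c(NA, NA, 0, 1), 1)
  expect_equal(unname(collapse_to_periods(m2, 2)[1, ]), c(NA, 1L))
  # 30 days to 15 periods: blocks of exactly 2 days
  m3 <- matrix(0L, 2, 30)
  m3[1, 29] <- 1L
  out <- collapse_to_periods(m3, 15)
  expect_equal(ncol(out), 15L)
  expect_equal(unname(out[1, ]), c(rep(0L, 14), 1L))
  # remainder days are front-loaded one per block
  m4 <- matrix(0L, 1, 7)
  m4[1, 3] <- 1L  # with blocks 3/2/2, day 3 falls in block 1
  expect_equal(unname(collapse_to_periods(m4, 3)[1, ]), c(1L, 0L, 0L))
  expect_error(collapse_to_periods(matrix(0, 1, 2), 3), "fewer days")
})

test_that("collapse preserves effort and detections", {
  set.seed(11)
  for (r in 1:10) {
    nd <- sample(15:40, 1)
    daily <- matrix(sample(c(0L, 1L, NA), 5 * nd, TRUE, c(0.6, 0.2, 0.2)), 5, nd)
    per <- collapse_to_periods(daily, sample(3:15, 1))
    # a sampled block never becomes NA; detections never invented or lost
    expect_equal(rowSums(per == 1, na.rm = TRUE) > 0,
                 rowSums(daily == 1, na.rm = TRUE) > 0)
    expect_true(all(rowSums(!is.na(per)) <= rowSums(!is.na(daily))))
    expect_true(all((rowSums(!is.na(per)) > 0) == (rowSums(!is.na(daily)) > 0)))
  }
})

test_that("species pooling is a union, idempotent, commutative and associative", {
  a <- matrix(c(1L, 0L, NA, 0L), 2)
  b <- matrix(c(0L, 0L, NA, 1L), 2)
  c3 <- matrix(c(0L, 1L, 0L, NA), 2)
  expect_equal(strip_attrs(pool_species(list(a, b))), matrix(c(1L, 0L, NA, 1L), 2))
  expect_equal(strip_attrs(pool_species(list(a, a))), strip_attrs(a))
  expect_equal(pool_species(list(a, b)), pool_species(list(b, a)),
               ignore_attr = TRUE)
  expect_equal(pool_species(list(pool_species(list(a, b)), c3)),
               pool_species(list(a, pool_species(list(b, c3)))),
               ignore_attr = TRUE)
  expect_error(pool_species(list(a, matrix(0L, 3, 2))), "mismatch")
})

test_that("covariate standardization centers, scales and one-hot expands", {
  cov <- data.frame(site_id = c("A", "B"), elevation = c(100, 300))
  out <- standardize_covariates(cov)
  expect_equal(out$elevation, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # idempotent up to numerical noise
  out2 <- standardize_covariates(out)
  expect_equal(out2$elevation, out$elevation, tolerance = 1e-12)
  expect_error(standardize_covariates(data.frame(site_id = "A", x = c(1, 1, 1))),
               "zero variance")
  f <- standardize_covariates(data.frame(site_id = c("A", "B", "C"),
                                         forest = c("montane", "cloud", "lowland")))
  # alphabetically first level (cloud) is the reference
  expect_named(f, c("site_id", "forest_lowland", "forest_montane"))
  expect_equal(f$forest_montane, c(1L, 0L, 0L))
})

test_that("detection matrices survive a CSV round trip cell-exactly", {
  tt <- make_toy_tables()
  m <- build_daily_matrix(tt$events, tt$deployments, "paca", 2010)
  pth <- withr::local_tempfile(fileext = ".csv")
  write_detection_matrix(m, pth)
  back <- read_detection_matrix(pth)
  expect_identical(strip_attrs(back), strip_attrs(m))
  expect_identical(rownames(back), rownames(m))
  expect_identical(attr(back, "species_id"), "paca")
})

test_that("sampled cells of a daily matrix equal total deployment effort", {
  tt <- make_toy_tables()
  m <- build_daily_matrix(tt$events, tt$deployments, "paca", 2010)
  effort <- sum(as.integer(tt$deployments$end_date - tt$deployments$start_date) + 1L)
  expect_equal(sum(!is.na(m)), effort)
})

test_that("naive occupancy counts sampled sites with a detection", {
  m <- rbind(c(1L, 0L), c(0L, 0L))
  expect_equal(naive_occupancy(m), 0.5)
  m2 <- rbind(c(1L, 0L), c(NA, NA))   # all-NA site leaves the denominator
  expect_equal(naive_occupancy(m2), 1)
})
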