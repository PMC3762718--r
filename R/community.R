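#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted draws containing
#' \code{ceiling(level * n)} of them.
#'
#' @param draws Numeric vector of at least 20 posterior draws.
#' @param level Coverage level, default 0.95.
#' @return Length-2 vector \code{c(lower, upper)}.
#' @export
hpdi <- function(draws, level = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 20L) stop("need at least 20 draws for an HPDI")
  x <- sort(draws)
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[seq.int(m, n)] - x[seq.int(1L, n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Half-sample mode of a posterior sample
#'
#' Deterministic mode estimator for skewed posteriors: recursively keeps the
#' shortest half of the sorted sample until at most two points remain, then
#' averages them. No bandwidth choice is involved, so repeated calls on the
#' same draws give the same value.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @return The estimated mode.
#' @export
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L) stop("need at least 100 draws for the mode estimator")
  x <- sort(draws)
  while (length(x) > 2L) {
    n <- length(x)
    m <- ceiling(n / 2)
    widths <- x[seq.int(m, n)] - x[seq.int(1L, n - m + 1L)]
    i <- which.min(widths)
    x <- x[seq.int(i, i + m - 1L)]
  }
  mean(x)
}

#' Assemble per-species occupancy posteriors
#'
#' Stacks the annual occupancy draws of independently fitted species into
#' one array for community indicators. Species are fitted independently, so
#' the m-th retained draw of each species is paired at each "model
#' iteration"; all species must therefore carry the same number of draws.
#'
#' @param fits Named list of \code{occudyn_mcmc} fits (names are species
#'   ids), or a named list of draws-x-years matrices.
#' @param species_attributes Optional data frame with \code{species_id} and
#'   grouping columns (\code{guild}, \code{hunted}, \code{iucn_status}).
#' @param type Occupancy flavour passed to [occupancy_draws].
#' @return Object of class \code{occupancy_posterior}: array
#'   \code{psi[species, year, draw]} plus the attribute table.
#' @export
occupancy_posterior <- function(fits, species_attributes = NULL,
                                type = c("fs", "expected")) {
  type <- match.arg(type)
  mats <- lapply(fits, function(f) {
    if (inherits(f, "occudyn_mcmc")) occupancy_draws(f, type) else as.matrix(f)
  })
  nd <- vapply(mats, nrow, 0L)
  if (length(unique(nd)) != 1L)
    stop("all species must have the same number of posterior draws")
  ny <- vapply(mats, ncol, 0L)
  if (length(unique(ny)) != 1L) stop("all species must span the same years")
  psi <- array(NA_real_, c(length(mats), ny[1L], nd[1L]),
               dimnames = list(names(mats), NULL, NULL))
  for (i in seq_along(mats)) psi[i, , ] <- t(mats[[i]])
  if (any(psi < 0 | psi > 1, na.rm = TRUE))
    stop("occupancy draws must lie in [0, 1]")
  structure(list(psi = psi, species = names(mats),
                 attributes = species_attributes),
            class = "occupancy_posterior")
}

#' Baseline-relative occupancy draws
#'
#' Scales each species' occupancy draws by the same draw's baseline-year
#' value, so the baseline column is identically 1. Draws with a zero
#' baseline are floored at 1e-6 and the species flagged.
#'
#' @param occ An [occupancy_posterior].
#' @param baseline Baseline year index, default 1.
#' @return An \code{occupancy_posterior} of relative occupancies, with a
#'   \code{floored} attribute naming any flagged species.
#' @export
relative_occupancy <- function(occ, baseline = 1L) {
  stopifnot(inherits(occ, "occupancy_posterior"))
  psi <- occ$psi
  base <- psi[, baseline, , drop = FALSE]
  floored <- occ$species[apply(base == 0, 1L, any)]
  base[base == 0] <- 1e-6
  rel <- sweep(psi, c(1L, 3L), base[, 1L, ], `/`)
  out <- occ
  out$psi <- rel
  attr(out, "floored") <- floored
  attr(out, "baseline") <- baseline
  out
}

#' Wildlife Picture Index series from occupancy posteriors
#'
#' The community index at each posterior draw and year is the geometric mean
#' over species of occupancy relative to the baseline year (so the baseline
#' value is exactly 1 at every draw). The per-year point estimate is the
#' smaller of the median and the half-sample mode of the draws, with a 95%
#' highest posterior density interval.
#'
#' @param occ An [occupancy_posterior] (absolute occupancies; they are
#'   rescaled internally).
#' @param subset Optional character vector of species ids (default: all).
#' @param level HPDI level.
#' @return Object of class \code{wpi_series}: list with \code{draws}
#'   (years x draws), \code{point}, \code{hpdi} (years x 2), \code{species}.
#' @export
wpi_series <- function(occ, subset = NULL, level = 0.95) {
  stopifnot(inherits(occ, "occupancy_posterior"))
  if (is.null(subset)) subset <- occ$species
  if (!length(subset)) stop("`subset` must name at least one species")
  miss <- setdiff(subset, occ$species)
  if (length(miss)) stop(sprintf("unknown species: %s", paste(miss, collapse = ", ")))
  rel <- relative_occupancy(occ)
  psi <- rel$psi[subset, , , drop = FALSE]
  wpi <- exp(apply(log(psi), c(2L, 3L), mean))   # years x draws
  point <- vapply(seq_len(nrow(wpi)), function(t) {
    dr <- wpi[t, ]
    if (max(dr) - min(dr) < 1e-12) return(dr[1L])
    if (length(dr) < 100L) return(stats::median(dr))  # mode needs more draws
    min(stats::median(dr), posterior_mode(dr))
  }, 0)
  hp <- t(apply(wpi, 1L, hpdi, level = level))
  structure(list(draws = wpi, point = point, hpdi = hp, species = subset,
                 baseline = 1L, level = level),
            class = "wpi_series")
}

#' @export
print.wpi_series <- function(x, ...) {
  cat(sprintf("Wildlife Picture Index (%d species, %d draws)\n",
              length(x$species), ncol(x$draws)))
  df <- data.frame(year = seq_along(x$point), wpi = round(x$point, 3),
                   hpdi_lo = round(x$hpdi[, 1L], 3),
                   hpdi_hi = round(x$hpdi[, 2L], 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Group-disaggregated Wildlife Picture Index
#'
#' Splits the community by a species attribute and computes the index per
#' group: hunted vs not hunted, functional guild, or IUCN status (least
#' concern vs species of conservation interest). Single-species groups are
#' permitted (the index is then that species' relative occupancy).
#'
#' @param occ An [occupancy_posterior] whose \code{attributes} table covers
#'   every species.
#' @param scheme \code{"hunted"}, \code{"guild"} or \code{"iucn"}.
#' @param level HPDI level.
#' @return Named list of [wpi_series], one per group.
#' @export
group_wpi <- function(occ, scheme = c("hunted", "guild", "iucn"), level = 0.95) {
  scheme <- match.arg(scheme)
  at <- occ$attributes
  if (is.null(at)) stop("`occ` carries no species attributes")
  at <- at[match(occ$species, at$species_id), ]
  if (any(is.na(at$species_id)))
    stop("attributes missing for some species")
  key <- switch(scheme,
    hunted = ifelse(at$hunted, "hunted", "not_hunted"),
    guild = as.character(at$guild),
    iucn = ifelse(at$iucn_status == "LC", "least_concern", "conservation_interest"))
  groups <- split(occ$species, key)
  lapply(groups, function(sp) wpi_series(occ, subset = sp, level = level))
}

#' Lambda matrix: posterior change ratios between years
#'
#' For every ordered year pair (t, t + n) computes the posterior draws of
#' the ratio \code{lambda = value(t + n) / value(t)} and classifies the
#' change by the 95% HPDI rule: \code{decline} if the upper bound is below
#' 1, \code{increase} if the lower bound is above 1, otherwise
#' \code{no_change}. Applies to a single species' occupancy draws or to a
#' community index series alike. Zero denominators are floored at 1e-6 and
#' flagged.
#'
#' @param x A \code{wpi_series}, an \code{occudyn_mcmc} fit (its annual
#'   occupancy draws are used), a years-x-draws matrix, or an
#'   [occupancy_posterior] with \code{species} naming one species.
#' @param species Species id when \code{x} is an \code{occupancy_posterior}.
#' @param level HPDI level.
#' @return Data frame with columns \code{from}, \code{to}, \code{lambda}
#'   (posterior median), \code{hpdi_lo}, \code{hpdi_hi}, \code{trend};
#'   attribute \code{floored} flags pairs with floored denominators.
#' @export
lambda_matrix <- function(x, species = NULL, level = 0.95) {
  draws <- if (inherits(x, "wpi_series")) {
    x$draws
  } else if (inherits(x, "occudyn_mcmc")) {
    t(occupancy_draws(x))
  } else if (inherits(x, "occupancy_posterior")) {
    if (is.null(species) || !species %in% x$species)
      stop("supply `species` naming one species of the posterior")
    x$psi[species, , ]
  } else as.matrix(x)
  n_years <- nrow(draws)
  if (n_years < 2L) stop("need at least 2 years")
  rows <- list()
  floored <- character()
  for (t in seq_len(n_years - 1L)) {
    den <- draws[t, ]
    if (any(den == 0)) {
      den[den == 0] <- 1e-6
      floored <- c(floored, sprintf("%d", t))
    }
    for (u in seq.int(t + 1L, n_years)) {
      lam <- draws[u, ] / den
      hp <- if (max(lam) - min(lam) < 1e-12) c(lam[1L], lam[1L]) else hpdi(lam, level)
      trend <- if (hp[2L] < 1) "decline" else if (hp[1L] > 1) "increase" else "no_change"
      rows[[length(rows) + 1L]] <-
        data.frame(from = t, to = u, lambda = stats::median(lam),
                   hpdi_lo = hp[1L], hpdi_hi = hp[2L], trend = trend,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "floored") <- unique(floored)
  out
}

#' Detection-corrected species richness from a regional pool
#'
#' Treats the species-by-sampling-point detection matrices (one per year,
#' rows spanning the regional pool, all-zero rows for pool members not
#' detected that year) as a dynamic occupancy problem in which the sampling
#' unit is a species and the within-year replicates are the camera points.
#' Detection is modeled on the logit scale with standardized log10 body
#' mass, trophic guild and an additive year effect; relative richness
#' \code{psi_S(t)} (the proportion of pool species present) follows the
#' year-specific survival/colonization recursion and is scaled by the pool
#' size to a species count. Confidence intervals come from a nonparametric
#' bootstrap resampling sampling points (500 iterations by default); both
#' the bootstrap standard error and the 95% percentile interval are
#' reported.
#'
#' @param y List with one species-x-sites 0/1/NA matrix per year, with
#'   species ids as row names.
#' @param attributes Data frame with \code{species_id}, \code{body_mass_kg}
#'   and \code{guild} covering every row of \code{y}.
#' @param pool_size Size of the regional species pool; must be at least the
#'   number of species ever detected.
#' @param n_boot Bootstrap iterations (default 500; 0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap resampling.
#' @param n_starts Optimizer starts per fit.
#' @return Object of class \code{richness_estimate}: data frame
#'   \code{estimates} (year, psi, richness, se, ci_lo, ci_hi), the detection
#'   coefficients, and the underlying [occudyn] fit.
#' @export
richness_fit <- function(y, attributes, pool_size, n_boot = 500L, seed = 1,
                         n_starts = 3L) {
  sp <- rownames(y[[1L]])
  if (is.null(sp)) stop("`y` matrices must carry species ids as row names")
  miss <- setdiff(sp, attributes$species_id)
  if (length(miss))
    stop(sprintf("no attributes for species: %s", paste(miss, collapse = ", ")))
  detected <- sum(vapply(seq_along(sp), function(i)
    any(vapply(y, function(m) any(m[i, ] == 1, na.rm = TRUE), NA)), NA))
  if (pool_size < detected)
    stop("`pool_size` is smaller than the number of species ever detected")
  at <- attributes[match(sp, attributes$species_id), ]
  lm10 <- log10(at$body_mass_kg)
  covs <- data.frame(
    log_mass = if (stats::sd(lm10) > 0) (lm10 - mean(lm10)) / stats::sd(lm10) else lm10 * 0,
    guild = factor(at$guild))
  single_guild <- nlevels(droplevels(covs$guild)) < 2L
  pf <- if (single_guild) ~log_mass else ~log_mass + guild
  fit_once <- function(ylist, start = NULL, starts = n_starts) {
    dat <- occu_data(ylist, site_covs = covs)
    occudyn(dat, psi = ~1, gamma = "year", phi = "year", p = "year",
            p_formula = pf, engine = "ml", n_starts = starts, seed = seed,
            start = start)
  }
  fit <- fit_once(y)
  psi_t <- fit$psi_annual
  n_years <- length(psi_t)
  boot_mat <- NULL
  se <- rep(NA_real_, n_years)
  ci <- matrix(NA_real_, n_years, 2L)
  if (n_boot > 0L) {
    n_sites <- ncol(y[[1L]])
    idx_list <- .with_seed(seed, {
      lapply(seq_len(n_boot), function(b)
        sample.int(n_sites, n_sites, replace = TRUE))
    })
    boot_mat <- matrix(NA_real_, n_boot, n_years)
    for (b in seq_len(n_boot)) {
      yb <- lapply(y, function(m) m[, idx_list[[b]], drop = FALSE])
      fb <- tryCatch(suppressWarnings(
        fit_once(yb, start = fit$coefficients, starts = 1L)),
        error = function(e) NULL)
      if (!is.null(fb)) boot_mat[b, ] <- fb$psi_annual
    }
    ok <- stats::complete.cases(boot_mat)
    se <- apply(boot_mat[ok, , drop = FALSE], 2L, stats::sd)
    ci <- t(apply(boot_mat[ok, , drop = FALSE], 2L, stats::quantile,
                  probs = c(0.025, 0.975)))
  }
  est <- data.frame(year = seq_len(n_years), psi = psi_t,
                    richness = scale_richness(psi_t, pool_size),
                    se = se * pool_size,
                    ci_lo = ci[, 1L] * pool_size, ci_hi = ci[, 2L] * pool_size,
                    naive = vapply(y, function(m)
                      sum(rowSums(m == 1, na.rm = TRUE) > 0), 0))
  structure(list(estimates = est, pool_size = pool_size,
                 detection_coefficients = fit$coefficients[grep("^p_", names(fit$coefficients))],
                 fit = fit, boot = boot_mat),
            class = "richness_estimate")
}

#' Scale relative richness by the regional pool
#'
#' @param psi Relative richness (proportion of pool species present).
#' @param pool_size Regional pool size.
#' @return Species count \code{psi * pool_size}.
#' @export
scale_richness <- function(psi, pool_size) {
  if (any(psi < 0 | psi > 1)) stop("`psi` must lie in [0, 1]")
  psi * pool_size
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Detection-corrected species richness (pool of %d)\n", x$pool_size))
  df <- x$estimates
  df[, -1L] <- round(df[, -1L], 2)
  print(df, row.names = FALSE)
  invisible(x)
}
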