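# Synthetic camera-trap communities drawn from the same generative model the
# occupancy analysis assumes, with the latent truth retained so downstream
# estimators can be checked against known values.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate site covariates along an altitudinal gradient
#'
#' Generates a covariate table emulating a tropical-forest transect: an
#' elevation gradient with canopy height and distance-to-edge correlated
#' with elevation through a Gaussian copula, plus slope, aspect and a
#' forest-type class cut from elevation.
#'
#' @param n_sites Number of camera points (the study design uses 60).
#' @param seed Integer seed; fixes all randomness.
#' @param elevation_range Range of the gradient in metres (default 30--3000).
#' @param canopy_cor,edge_cor Latent-normal correlation of canopy height and
#'   edge distance with elevation (0 gives independent covariates).
#' @return Data frame with columns \code{site_id}, \code{elevation},
#'   \code{canopy_height}, \code{edge_distance}, \code{slope}, \code{aspect},
#'   \code{forest_type}.
#' @export
simulate_site_covariates <- function(n_sites, seed = 1,
                                     elevation_range = c(30, 3000),
                                     canopy_cor = 0.6, edge_cor = 0.4) {
  stopifnot(n_sites >= 1, abs(canopy_cor) <= 1, abs(edge_cor) <= 1)
  .with_seed(seed, {
    ze <- stats::rnorm(n_sites)
    zc <- canopy_cor * ze + sqrt(1 - canopy_cor^2) * stats::rnorm(n_sites)
    zd <- edge_cor * ze + sqrt(1 - edge_cor^2) * stats::rnorm(n_sites)
    elevation <- elevation_range[1] + diff(elevation_range) * stats::pnorm(ze)
    data.frame(
      site_id = sprintf("CT-%03d", seq_len(n_sites)),
      elevation = elevation,
      canopy_height = 8 + 32 * stats::pnorm(zc),
      edge_distance = 5000 * stats::pnorm(zd),
      slope = stats::runif(n_sites, 0, 60),
      aspect = stats::runif(n_sites, 0, 360),
      forest_type = cut(elevation, c(-Inf, 800, 2000, Inf),
                        labels = c("lowland", "montane", "cloud")),
      stringsAsFactors = FALSE
    )
  })
}

#' Per-species simulation parameters
#'
#' @param beta_psi Named logit-scale coefficients for year-1 occupancy; the
#'   first element is the intercept, subsequent names must match covariate
#'   columns.
#' @param phi,gamma Survival and colonization probabilities per transition
#'   (length \code{n_years - 1} or 1).
#' @param p Per-period detection probability per year (length \code{n_years}
#'   or 1).
#' @param species_id Optional label.
#' @return Object of class \code{species_params}.
#' @export
species_params <- function(beta_psi, phi, gamma, p, species_id = NULL) {
  if (any(!is.finite(beta_psi))) stop("`beta_psi` must be finite")
  for (v in list(phi = phi, gamma = gamma, p = p))
    if (any(v < 0 | v > 1)) stop("phi, gamma and p must lie in [0, 1]")
  structure(list(beta_psi = beta_psi, phi = phi, gamma = gamma, p = p,
                 species_id = species_id),
            class = "species_params")
}

#' Simulate one species' latent states and detection histories
#'
#' Draws year-1 occupancy \code{Z} from Bernoulli(plogis(X beta)), propagates
#' it across years with survival \code{phi} and colonization \code{gamma}
#' (closure within years), and draws period observations Bernoulli(Z p).
#' Detections are generated only at occupied site-years.
#'
#' @param params A [species_params] object.
#' @param covariates Covariate data frame (one row per site) supplying any
#'   columns named in \code{beta_psi}; may be \code{NULL} for intercept-only.
#' @param n_sites Required when \code{covariates} is \code{NULL}.
#' @param n_years,n_periods Study dimensions.
#' @param seed Integer seed.
#' @param unit \code{"period"} (the analysis unit) or \code{"day"}, in which
#'   case \code{n_periods} is interpreted as days and \code{p} as a daily
#'   probability (used to exercise the day-to-period collapse).
#' @return List with \code{Z} (sites x years truth), \code{data} (an
#'   [occu_data]), \code{psi1} (per-site year-1 occupancy probability) and
#'   \code{params}.
#' @export
simulate_species <- function(params, covariates = NULL, n_sites = NULL,
                             n_years, n_periods, seed = 1, unit = "period") {
  stopifnot(inherits(params, "species_params"))
  if (is.null(covariates)) {
    if (is.null(n_sites)) stop("supply `covariates` or `n_sites`")
    X <- matrix(1, n_sites, 1L)
    if (length(params$beta_psi) != 1L)
      stop("`beta_psi` has covariate terms but no covariates were supplied")
  } else {
    n_sites <- nrow(covariates)
    nms <- names(params$beta_psi)[-1L]
    miss <- setdiff(nms, names(covariates))
    if (length(miss))
      stop(sprintf("covariates missing column(s): %s", paste(miss, collapse = ", ")))
    X <- cbind(1, as.matrix(covariates[nms]))
  }
  phi <- .recycle_par(params$phi, max(n_years - 1L, 1L), "phi")
  gamma <- .recycle_par(params$gamma, max(n_years - 1L, 1L), "gamma")
  p <- .recycle_par(params$p, n_years, "p")
  psi1 <- stats::plogis(drop(X %*% params$beta_psi))
  .with_seed(seed, {
    Z <- matrix(0L, n_sites, n_years)
    Z[, 1L] <- stats::rbinom(n_sites, 1L, psi1)
    if (n_years > 1L) for (t in 2:n_years) {
      pr <- ifelse(Z[, t - 1L] == 1L, phi[t - 1L], gamma[t - 1L])
      Z[, t] <- stats::rbinom(n_sites, 1L, pr)
    }
    y <- lapply(seq_len(n_years), function(t) {
      m <- matrix(stats::rbinom(n_sites * n_periods, 1L, rep(Z[, t] * p[t], n_periods)),
                  n_sites, n_periods)
      rownames(m) <- sprintf("CT-%03d", seq_len(n_sites))
      m
    })
    list(Z = Z,
         data = occu_data(y, site_covs = covariates, species_id = params$species_id),
         psi1 = psi1, params = params, unit = unit)
  })
}

#' Impose camera-failure missingness on a detection matrix
#'
#' Replaces cells with \code{NA} to emulate inactive cameras. In
#' \code{"iid"} mode each cell is independently missing with probability
#' \code{miss_prob}; in \code{"tail"} mode a site's camera dies with
#' probability \code{miss_prob} at a uniformly drawn period and all later
#' periods of that site become \code{NA}. Detections are never invented.
#'
#' @param matrix Ternary detection matrix.
#' @param miss_prob Missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @param mode \code{"iid"} (default) or \code{"tail"}.
#' @return Matrix of the same shape with additional \code{NA}s.
#' @export
apply_missingness <- function(matrix, miss_prob, seed = 1, mode = c("iid", "tail")) {
  mode <- match.arg(mode)
  if (miss_prob < 0 || miss_prob >= 1) stop("`miss_prob` must be in [0, 1)")
  if (miss_prob == 0) return(matrix)
  .with_seed(seed, {
    if (mode == "iid") {
      drop <- matrix(stats::runif(length(matrix)) < miss_prob, nrow(matrix))
    } else {
      drop <- matrix(FALSE, nrow(matrix), ncol(matrix))
      dies <- stats::runif(nrow(matrix)) < miss_prob
      at <- sample.int(ncol(matrix), nrow(matrix), replace = TRUE)
      for (j in which(dies)) drop[j, seq(at[j], ncol(matrix))] <- TRUE
    }
    matrix[drop] <- NA_integer_
    matrix
  })
}

# Preset community: 13 focal species spanning the guild/detectability range
# of a neotropical terrestrial mammal community, with hunted small herbivores
# flagged. Stable preset derives gamma for stationarity
# (gamma = psi (1 - phi) / (1 - psi), so expected occupancy is constant);
# the decline preset lowers survival of the hunted small herbivores so their
# occupancy roughly halves over three transitions.
.preset_species <- function(preset) {
  tab <- data.frame(
    species_id = c("paca", "agouti", "armadillo", "tayra", "ocelot", "margay",
                   "red_brocket", "coati", "jaguar", "peccary", "puma",
                   "jaguarundi", "tapir"),
    psi1 = c(0.65, 0.60, 0.50, 0.35, 0.45, 0.20, 0.50, 0.55, 0.15, 0.60,
             0.20, 0.18, 0.40),
    phi  = c(0.85, 0.85, 0.80, 0.80, 0.85, 0.80, 0.85, 0.80, 0.80, 0.85,
             0.80, 0.80, 0.85),
    p    = c(0.35, 0.40, 0.30, 0.20, 0.25, 0.15, 0.30, 0.30, 0.12, 0.45,
             0.12, 0.12, 0.25),
    body_mass_kg = c(8, 3, 4, 5, 12, 4, 25, 4.5, 60, 25, 50, 6, 250),
    guild = c("small_herbivore", "small_herbivore", "omnivore", "omnivore",
              "carnivore", "carnivore", "large_herbivore", "omnivore",
              "carnivore", "large_herbivore", "carnivore", "carnivore",
              "large_herbivore"),
    hunted = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               TRUE, FALSE, FALSE, FALSE),
    iucn_status = c("LC", "LC", "LC", "LC", "LC", "NT", "DD", "LC", "NT",
                    "LC", "LC", "LC", "EN"),
    stringsAsFactors = FALSE
  )
  tab$gamma <- tab$psi1 * (1 - tab$phi) / (1 - tab$psi1)
  if (preset == "hunted_decline") {
    idx <- tab$hunted & tab$guild == "small_herbivore"
    tab$phi[idx] <- 0.78
    tab$gamma[idx] <- 0.02
  }
  tab
}

#' Define a synthetic community scenario
#'
#' @param preset \code{"stable"} (all species at their stationary occupancy,
#'   so the true community index is 1 every year) or \code{"hunted_decline"}
#'   (hunted small herbivores lose roughly half their occupancy over three
#'   year-to-year transitions; all other species stable).
#' @param n_sites,n_years,n_periods Study dimensions; defaults mirror the
#'   60-point, 5-season, 15-period design.
#' @param miss_prob Per-cell probability a site-period is unsampled,
#'   shared across species (cameras fail for all species at once).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class \code{community_scenario}.
#' @export
community_scenario <- function(preset = c("stable", "hunted_decline"),
                               n_sites = 60, n_years = 5, n_periods = 15,
                               miss_prob = 0.03, seed = 1) {
  preset <- match.arg(preset)
  stopifnot(n_sites >= 1, n_years >= 1, n_periods >= 1,
            miss_prob >= 0, miss_prob < 1)
  structure(list(preset = preset, n_sites = as.integer(n_sites),
                 n_years = as.integer(n_years),
                 n_periods = as.integer(n_periods),
                 miss_prob = miss_prob, seed = as.integer(seed)),
            class = "community_scenario")
}

#' Read a scenario from a YAML/JSON-style config
#'
#' @param config Path to a YAML file or a named list with any of the
#'   [community_scenario] arguments.
#' @return A \code{community_scenario}.
#' @export
scenario_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  do.call(community_scenario, config[intersect(names(config),
    names(formals(community_scenario)))])
}

#' Simulate a full camera-trap community with known truth
#'
#' Draws every species of the scenario preset from the dynamic occupancy
#' generative model, imposes a shared camera-failure missingness pattern,
#' and returns the observed detection histories alongside the latent truth
#' (occupancy states, parameters and expected occupancy trajectories),
#' sufficient to compute the true community index.
#'
#' @param scenario A [community_scenario] (or arguments passed to it).
#' @return Object of class \code{community_sim}: list with \code{species}
#'   (per species: \code{data}, \code{Z}, \code{params}), \code{covariates},
#'   \code{attributes}, \code{truth} (expected occupancy matrix
#'   \code{psi_expected}, true baseline-relative index \code{wpi_true}) and
#'   the \code{scenario}.
#' @export
simulate_community <- function(scenario = community_scenario()) {
  if (!inherits(scenario, "community_scenario"))
    scenario <- do.call(community_scenario, as.list(scenario))
  tab <- .preset_species(scenario$preset)
  covs <- simulate_site_covariates(scenario$n_sites, seed = scenario$seed)
  # one shared NA pattern per year: cameras fail for every species alike
  pattern <- .with_seed(scenario$seed + 7L, {
    lapply(seq_len(scenario$n_years), function(t)
      matrix(stats::runif(scenario$n_sites * scenario$n_periods) < scenario$miss_prob,
             scenario$n_sites))
  })
  species <- vector("list", nrow(tab))
  names(species) <- tab$species_id
  psi_exp <- matrix(NA_real_, nrow(tab), scenario$n_years,
                    dimnames = list(tab$species_id, NULL))
  for (i in seq_len(nrow(tab))) {
    pars <- species_params(beta_psi = stats::qlogis(tab$psi1[i]),
                           phi = tab$phi[i], gamma = tab$gamma[i], p = tab$p[i],
                           species_id = tab$species_id[i])
    sim <- simulate_species(pars, n_sites = scenario$n_sites,
                            n_years = scenario$n_years,
                            n_periods = scenario$n_periods,
                            seed = scenario$seed + 100L + i)
    y <- lapply(seq_along(sim$data$y), function(t) {
      m <- sim$data$y[[t]]
      m[pattern[[t]]] <- NA_integer_
      m
    })
    sim$data <- occu_data(y, site_covs = covs, species_id = tab$species_id[i])
    species[[i]] <- sim
    traj <- numeric(scenario$n_years)
    traj[1L] <- tab$psi1[i]
    if (scenario$n_years > 1L) for (t in 2:scenario$n_years)
      traj[t] <- occupancy_recursion(traj[t - 1L], tab$phi[i], tab$gamma[i])
    psi_exp[i, ] <- traj
  }
  rel <- psi_exp / psi_exp[, 1L]
  attributes_df <- tab[c("species_id", "body_mass_kg", "guild", "hunted", "iucn_status")]
  structure(list(
    species = species,
    covariates = covs,
    attributes = attributes_df,
    truth = list(psi_expected = psi_exp,
                 params = tab,
                 wpi_true = exp(colMeans(log(rel)))),
    scenario = scenario
  ), class = "community_sim")
}

#' @export
print.community_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("Synthetic camera-trap community ('%s' preset)\n", s$preset))
  cat(sprintf("  %d species, %d sites, %d years, %d periods, miss_prob %.2f, seed %d\n",
              length(x$species), s$n_sites, s$n_years, s$n_periods,
              s$miss_prob, s$seed))
  cat("  true community index by year:",
      paste(sprintf("%.3f", x$truth$wpi_true), collapse = ", "), "\n")
  invisible(x)
}
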