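#' Fit a multi-season (dynamic) occupancy model
#'
#' Fits the hierarchical model in which a species' presence at each site is a
#' latent Bernoulli state -- year-1 occupancy on the logit scale as a
#' function of site covariates, year-to-year transitions governed by
#' apparent survival \code{phi} and colonization \code{gamma}, and period
#' observations Bernoulli(Z p) with detection probability \code{p} -- either
#' by marginalized maximum likelihood (latent states summed out by forward
#' recursion; used for AIC model selection) or by a Gibbs/Metropolis sampler
#' (used for posterior inference and all derived community indicators).
#'
#' @param data An [occu_data] object.
#' @param psi Formula for year-1 occupancy covariates (default \code{~1}).
#' @param gamma,phi \code{"year"} for year-specific transition probabilities
#'   or \code{"constant"}.
#' @param p \code{"constant"} or \code{"year"} detection probability.
#' @param p_formula Optional formula of row covariates on detection (logit
#'   scale, additive with the year effect); used by the species-richness
#'   model. Only supported by the ML engine.
#' @param engine \code{"ml"} or \code{"mcmc"}.
#' @param mcmc An [mcmc_control] (MCMC engine only).
#' @param n_starts Number of optimizer starts (ML engine); the first start
#'   is a data-driven heuristic, the rest are seeded random perturbations.
#' @param seed Integer seed for the random restarts / the sampler.
#' @return An object of class \code{occudyn} (ML) or
#'   \code{c("occudyn_mcmc", "occudyn")} with the usual
#'   \code{print}/\code{summary}/\code{coef}/\code{predict}/\code{plot}/
#'   \code{simulate}/\code{residuals}/\code{logLik} methods.
#' @examples
#' sim <- simulate_species(species_params(0, phi = 0.8, gamma = 0.1, p = 0.4),
#'                         n_sites = 50, n_years = 3, n_periods = 10, seed = 1)
#' fit <- occudyn(sim$data, gamma = "constant", phi = "constant")
#' coef(fit)
#' @export
occudyn <- function(data, psi = ~1, gamma = c("year", "constant"),
                    phi = c("year", "constant"), p = c("constant", "year"),
                    p_formula = NULL, engine = c("ml", "mcmc"),
                    mcmc = mcmc_control(), n_starts = 5, seed = 1,
                    start = NULL) {
  stopifnot(inherits(data, "occu_data"))
  gamma <- match.arg(gamma)
  phi <- match.arg(phi)
  p <- match.arg(p)
  engine <- match.arg(engine)
  st <- .detection_stats(data$y)
  if (!any(st$K > 0)) stop("need at least one site with a sampled period")
  n_years <- ncol(st$d)
  if (n_years < 2L) {
    gamma <- "constant"
    phi <- "constant"
  }
  X <- .psi_design(data, psi)
  structure_ <- list(psi = psi, gamma = gamma, phi = phi, p = p,
                     p_formula = p_formula)
  if (engine == "mcmc") {
    if (!is.null(p_formula))
      stop("`p_formula` is only supported by the ML engine")
    return(.fit_mcmc(data, st, X, structure_, mcmc, call = match.call()))
  }
  .fit_ml(data, st, X, structure_, n_starts = n_starts, seed = seed,
          start = start, call = match.call())
}

# --- parameter packing ----------------------------------------------------

.par_layout <- function(X, structure_, n_years, data) {
  nb <- ncol(X)
  nphi <- if (n_years < 2L) 0L else if (structure_$phi == "year") n_years - 1L else 1L
  ngam <- if (n_years < 2L) 0L else if (structure_$gamma == "year") n_years - 1L else 1L
  W <- NULL
  if (!is.null(structure_$p_formula)) {
    if (is.null(data$site_covs)) stop("`p_formula` requires site covariates")
    W <- stats::model.matrix(structure_$p_formula, data$site_covs)
    np <- ncol(W) + if (structure_$p == "year") n_years - 1L else 0L
  } else {
    np <- if (structure_$p == "year") n_years else 1L
  }
  nm_beta <- paste0("psi_", colnames(X))
  nm_phi <- if (nphi == 1L) "phi" else if (nphi) paste0("phi_", seq_len(nphi)) else character()
  nm_gam <- if (ngam == 1L) "gamma" else if (ngam) paste0("gamma_", seq_len(ngam)) else character()
  nm_p <- if (!is.null(W)) {
    c(paste0("p_", colnames(W)),
      if (structure_$p == "year") paste0("p_year", 2:n_years) else character())
  } else if (np == 1L) "p" else paste0("p_", seq_len(np))
  list(nb = nb, nphi = nphi, ngam = ngam, np = np, W = W,
       names = c(nm_beta, nm_phi, nm_gam, nm_p), n_years = n_years)
}

.unpack_theta <- function(theta, lay) {
  i <- 0L
  beta <- theta[seq_len(lay$nb)]; i <- lay$nb
  phi <- stats::plogis(theta[i + seq_len(lay$nphi)]); i <- i + lay$nphi
  gam <- stats::plogis(theta[i + seq_len(lay$ngam)]); i <- i + lay$ngam
  pth <- theta[i + seq_len(lay$np)]
  list(beta = beta, phi = phi, gamma = gam, p_theta = pth)
}

.pmat_from_theta <- function(pth, lay, n_sites) {
  n_years <- lay$n_years
  if (!is.null(lay$W)) {
    eta <- drop(lay$W %*% pth[seq_len(ncol(lay$W))])
    em <- matrix(eta, n_sites, n_years)
    if (length(pth) > ncol(lay$W)) {
      yr <- c(0, pth[-seq_len(ncol(lay$W))])
      em <- sweep(em, 2L, yr, `+`)
    }
    stats::plogis(em)
  } else if (length(pth) == 1L) {
    matrix(stats::plogis(pth), n_sites, n_years)
  } else {
    matrix(stats::plogis(pth), n_sites, n_years, byrow = TRUE)
  }
}

.expand_trans <- function(v, n_years) {
  if (n_years < 2L) return(numeric())
  if (length(v) == 1L) rep(v, n_years - 1L) else v
}

# --- ML engine ------------------------------------------------------------

.fit_ml <- function(data, st, X, structure_, n_starts, seed, call,
                    start = NULL) {
  n <- nrow(st$d)
  n_years <- ncol(st$d)
  lay <- .par_layout(X, structure_, n_years, data)
  nll <- function(theta) {
    up <- .unpack_theta(theta, lay)
    psi1 <- stats::plogis(drop(X %*% up$beta))
    phi <- .expand_trans(up$phi, n_years)
    gam <- .expand_trans(up$gamma, n_years)
    pmat <- .pmat_from_theta(up$p_theta, lay, n)
    ll <- .loglik_sites(st$d, st$K, psi1, phi, gam, pmat)
    v <- -sum(ll)
    if (!is.finite(v)) v <- 1e10
    v
  }
  # heuristic start from the naive occupancy and modest detectability
  naive1 <- mean(st$d[st$K[, 1L] > 0, 1L] > 0)
  start0 <- if (!is.null(start)) {
    if (length(start) != length(lay$names)) stop("`start` has the wrong length")
    unname(start)
  } else {
    c(stats::qlogis(min(max(naive1, 0.05), 0.95)), rep(0, lay$nb - 1L),
      rep(stats::qlogis(0.7), lay$nphi), rep(stats::qlogis(0.15), lay$ngam),
      rep(stats::qlogis(0.25), lay$np))
  }
  starts <- list(start0)
  if (n_starts > 1L) {
    starts <- c(starts, .with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i)
        start0 + stats::rnorm(length(start0), 0, 1))
    }))
  }
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("optimization failed from every start")
  theta <- stats::setNames(best$par, lay$names)
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) {
    dv <- diag(vc)
    s <- sqrt(pmax(dv, 0))
    s[!is.finite(dv) | dv <= 0] <- NA_real_
    stats::setNames(s, lay$names)
  } else stats::setNames(rep(NA_real_, length(theta)), lay$names)
  up <- .unpack_theta(theta, lay)
  prob_idx <- seq.int(lay$nb + 1L, length(theta))
  boundary <- length(prob_idx) > 0 && any(abs(theta[prob_idx]) > 8)
  psi1 <- stats::plogis(drop(X %*% up$beta))
  phi <- .expand_trans(up$phi, n_years)
  gam <- .expand_trans(up$gamma, n_years)
  psi_site <- matrix(NA_real_, n, n_years)
  psi_site[, 1L] <- psi1
  if (n_years > 1L) for (t in 2:n_years)
    psi_site[, t] <- occupancy_recursion(psi_site[, t - 1L], phi[t - 1L], gam[t - 1L])
  ll <- -best$value
  k <- length(theta)
  out <- list(call = call, data = data, structure = structure_, layout = lay,
              X = X, coefficients = theta, se = se, vcov = vc,
              params = list(beta_psi = up$beta, phi = phi, gamma = gam,
                            p = .pmat_from_theta(up$p_theta, lay, n)[1L, ],
                            pmat = .pmat_from_theta(up$p_theta, lay, n)),
              psi_site = psi_site, psi_annual = colMeans(psi_site),
              naive = vapply(data$y, naive_occupancy, 0),
              logLik = ll, AIC = 2 * k - 2 * ll, n_params = k,
              convergence = conv, boundary = boundary, engine = "ml")
  class(out) <- "occudyn"
  if (!conv) warning("optimizer did not report convergence")
  if (boundary) out$boundary_message <- "one or more probability estimates at the boundary (|logit| > 8)"
  out
}

#' The candidate model structures for species fits
#'
#' The six multi-season structures used for per-species model selection:
#' a fully constant null model, null-occupancy models with year-specific
#' dynamics (with constant or year-specific detection), and year-1 occupancy
#' covariate models (elevation; elevation + canopy height; elevation +
#' distance to edge) with year-specific dynamics.
#'
#' @param null_only If \code{TRUE}, return only the three structures without
#'   occupancy covariates (used for sparsely detected species).
#' @return Named list of argument lists for [occudyn].
#' @export
candidate_models <- function(null_only = FALSE) {
  cands <- list(
    "psi(.)gam(yr)phi(yr)p(.)" =
      list(psi = ~1, gamma = "year", phi = "year", p = "constant"),
    "psi(.)gam(yr)phi(yr)p(yr)" =
      list(psi = ~1, gamma = "year", phi = "year", p = "year"),
    "psi(.)gam(.)phi(.)p(.)" =
      list(psi = ~1, gamma = "constant", phi = "constant", p = "constant"),
    "psi(Ele)gam(yr)phi(yr)p(.)" =
      list(psi = ~elevation, gamma = "year", phi = "year", p = "constant"),
    "psi(Ele+Can)gam(yr)phi(yr)p(.)" =
      list(psi = ~elevation + canopy_height, gamma = "year", phi = "year",
           p = "constant"),
    "psi(Ele+Edg)gam(yr)phi(yr)p(.)" =
      list(psi = ~elevation + edge_distance, gamma = "year", phi = "year",
           p = "constant")
  )
  if (null_only) cands[1:3] else cands
}

#' Fit every candidate structure to one species
#'
#' @param data An [occu_data].
#' @param candidates Named list of structure argument lists (default
#'   [candidate_models()]).
#' @param engine,seed,n_starts Passed to [occudyn].
#' @param ... Further arguments to [occudyn].
#' @return Named list of fits.
#' @export
fit_candidates <- function(data, candidates = candidate_models(),
                           engine = "ml", seed = 1, n_starts = 5, ...) {
  out <- lapply(names(candidates), function(nm) {
    args <- c(list(data = data, engine = engine, seed = seed,
                   n_starts = n_starts), candidates[[nm]], list(...))
    do.call(occudyn, args)
  })
  stats::setNames(out, names(candidates))
}
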