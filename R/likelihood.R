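#' Probability of a within-year detection history
#'
#' Computes the probability of one site's detection history for a single
#' year, conditional on the latent occupancy state. Observations are
#' Bernoulli(z * p) per sampling period; \code{NA} marks periods the site was
#' not sampled and contributes no information.
#'
#' @param history Ternary vector of period observations: 1 (detected),
#'   0 (sampled, not detected) or \code{NA} (not sampled).
#' @param p Per-period detection probability, a single value in \[0, 1\].
#' @param z Latent occupancy state, 0 or 1.
#' @return A probability. An all-\code{NA} history returns 1 for either state.
#' @examples
#' within_year_prob(c(1, 0), p = 0.5, z = 1) # 0.25
#' within_year_prob(c(1, 0), p = 0.5, z = 0) # 0 (detection impossible)
#' @export
within_year_prob <- function(history, p, z) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]")
  if (length(z) != 1L || !z %in% c(0, 1))
    stop("`z` must be 0 or 1")
  h <- history[!is.na(history)]
  if (length(h) && !all(h %in% c(0, 1)))
    stop("detection history entries must be 0, 1 or NA")
  if (!length(h)) return(1)
  if (z == 0) return(as.numeric(!any(h == 1)))
  d <- sum(h == 1)
  p^d * (1 - p)^(length(h) - d)
}

#' Marginal likelihood of one site's multi-year detection history
#'
#' Exact marginal probability of a site's detection histories over all years,
#' summing over the latent occupancy sequence by forward recursion. Year-1
#' occupancy is \code{psi1} (or \code{plogis(sum(beta * x))} when a
#' coefficient vector and covariate row are supplied); between years an
#' occupied site persists with probability \code{phi} (apparent survival) and
#' an empty site is colonized with probability \code{gamma}. Within a year the
#' state is closed.
#'
#' @param histories List with one ternary period vector per year (a matrix is
#'   taken row-per-year).
#' @param psi1 Year-1 occupancy probability. Ignored when \code{beta} is given.
#' @param phi,gamma Survival and colonization probabilities; length
#'   \code{n_years - 1} or length 1 (recycled).
#' @param p Detection probability per year; length \code{n_years} or 1.
#' @param beta,x Optional logit-scale coefficient vector and matching
#'   covariate row (including the intercept term) defining
#'   \code{psi1 = plogis(sum(beta * x))}.
#' @return The marginal probability of the full history (a value in \[0, 1\]).
#' @examples
#' site_likelihood(list(c(1, 0)), psi1 = 0.5, p = 0.5)          # 0.125
#' site_likelihood(list(c(0, 0)), psi1 = 0.4, p = 0.5)          # 0.7
#' site_likelihood(list(1, 0), psi1 = 0.5, phi = 0.8, gamma = 0.2, p = 0.5)
#' @export
site_likelihood <- function(histories, psi1 = NULL, phi = NULL, gamma = NULL,
                            p, beta = NULL, x = NULL) {
  if (is.matrix(histories)) histories <- split(histories, row(histories))
  if (!is.list(histories)) histories <- list(histories)
  n_years <- length(histories)
  if (!is.null(beta)) {
    if (is.null(x)) x <- 1
    if (length(beta) != length(x)) stop("`beta` and `x` lengths differ")
    psi1 <- stats::plogis(sum(beta * x))
  }
  if (is.null(psi1) || length(psi1) != 1L || psi1 < 0 || psi1 > 1)
    stop("`psi1` must be a single probability in [0, 1]")
  p <- .recycle_par(p, n_years, "p")
  if (n_years > 1L) {
    phi <- .recycle_par(phi, n_years - 1L, "phi")
    gamma <- .recycle_par(gamma, n_years - 1L, "gamma")
  }
  a1 <- psi1 * within_year_prob(histories[[1L]], p[1L], 1)
  a0 <- (1 - psi1) * within_year_prob(histories[[1L]], p[1L], 0)
  if (n_years > 1L) {
    for (t in 2:n_years) {
      f1 <- within_year_prob(histories[[t]], p[t], 1)
      f0 <- within_year_prob(histories[[t]], p[t], 0)
      n1 <- (a1 * phi[t - 1L] + a0 * gamma[t - 1L]) * f1
      n0 <- (a1 * (1 - phi[t - 1L]) + a0 * (1 - gamma[t - 1L])) * f0
      a1 <- n1
      a0 <- n0
    }
  }
  a1 + a0
}

.recycle_par <- function(v, len, name) {
  if (is.null(v)) stop(sprintf("`%s` is required", name))
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop(sprintf("`%s` must contain probabilities in [0, 1]", name))
  if (length(v) == 1L) return(rep(v, len))
  if (length(v) != len)
    stop(sprintf("`%s` must have length 1 or %d", name, len))
  v
}

#' One-step occupancy recursion
#'
#' Expected occupancy the following year given survival of occupied sites and
#' colonization of empty ones:
#' \code{psi' = psi * phi + (1 - psi) * gamma}.
#'
#' @param psi,phi,gamma Probabilities in \[0, 1\] (vectorized).
#' @return Occupancy probability for the next year.
#' @export
occupancy_recursion <- function(psi, phi, gamma) {
  for (v in list(psi, phi, gamma))
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("all arguments must be probabilities in [0, 1]")
  psi * phi + (1 - psi) * gamma
}

# Sufficient statistics of a detection-history list: per site x year, the
# count of detections (d) and of sampled periods (K). The within-year
# likelihood depends on the history only through (d, K).
.detection_stats <- function(ylist) {
  d <- vapply(ylist, function(m) rowSums(m == 1, na.rm = TRUE), numeric(nrow(ylist[[1L]])))
  K <- vapply(ylist, function(m) rowSums(!is.na(m)), numeric(nrow(ylist[[1L]])))
  if (nrow(ylist[[1L]]) == 1L) {
    d <- matrix(d, nrow = 1L)
    K <- matrix(K, nrow = 1L)
  }
  list(d = d, K = K)
}

# Vectorized per-site log-likelihoods via the scaled forward recursion.
# d, K: n x T matrices; psi1: length-n vector; phi, gamma: length T-1;
# pmat: n x T matrix of detection probabilities.
.loglik_sites <- function(d, K, psi1, phi, gamma, pmat) {
  n <- nrow(d)
  n_years <- ncol(d)
  l1 <- pmat[, 1L]^d[, 1L] * (1 - pmat[, 1L])^(K[, 1L] - d[, 1L])
  l0 <- as.numeric(d[, 1L] == 0)
  a1 <- psi1 * l1
  a0 <- (1 - psi1) * l0
  s <- a1 + a0
  ll <- log(s)
  a1 <- a1 / s
  a0 <- a0 / s
  if (n_years > 1L) {
    for (t in 2:n_years) {
      l1 <- pmat[, t]^d[, t] * (1 - pmat[, t])^(K[, t] - d[, t])
      l0 <- as.numeric(d[, t] == 0)
      b1 <- (a1 * phi[t - 1L] + a0 * gamma[t - 1L]) * l1
      b0 <- (a1 * (1 - phi[t - 1L]) + a0 * (1 - gamma[t - 1L])) * l0
      s <- b1 + b0
      ll <- ll + log(s)
      a1 <- b1 / s
      a0 <- b0 / s
    }
  }
  ll
}

#' Negative log-likelihood of a multi-season occupancy model
#'
#' Sum of per-site negative log marginal likelihoods over independent sites.
#' Sites never sampled in any year contribute zero.
#'
#' @param data An [occu_data] object.
#' @param params List with elements \code{beta_psi} (logit-scale year-1
#'   occupancy coefficients, intercept first), \code{phi}, \code{gamma}
#'   (length \code{n_years - 1} or 1) and \code{p} (length \code{n_years}, 1,
#'   or an \code{n_sites x n_years} matrix).
#' @param psi_formula Formula selecting site covariates for year-1 occupancy;
#'   default intercept-only.
#' @return The negative log-likelihood (a single number).
#' @export
neg_log_likelihood <- function(data, params, psi_formula = ~1) {
  stopifnot(inherits(data, "occu_data"))
  st <- .detection_stats(data$y)
  n <- nrow(st$d)
  n_years <- ncol(st$d)
  X <- .psi_design(data, psi_formula)
  if (length(params$beta_psi) != ncol(X))
    stop("`beta_psi` length does not match the year-1 occupancy design matrix")
  psi1 <- stats::plogis(drop(X %*% params$beta_psi))
  phi <- if (n_years > 1L) .recycle_par(params$phi, n_years - 1L, "phi") else numeric()
  gamma <- if (n_years > 1L) .recycle_par(params$gamma, n_years - 1L, "gamma") else numeric()
  pmat <- if (is.matrix(params$p)) params$p else
    matrix(.recycle_par(params$p, n_years, "p"), n, n_years, byrow = TRUE)
  ll <- .loglik_sites(st$d, st$K, psi1, phi, gamma, pmat)
  if (any(!is.finite(ll))) {
    bad <- rownames(data$y[[1L]])[which(!is.finite(ll))[1L]]
    stop(sprintf("non-finite site likelihood at site '%s'", bad))
  }
  -sum(ll)
}

.is_intercept_only <- function(f) {
  length(attr(stats::terms(f), "term.labels")) == 0L
}

.psi_design <- function(data, psi_formula) {
  if (is.null(psi_formula) || .is_intercept_only(psi_formula))
    return(matrix(1, nrow(data$y[[1L]]), 1L, dimnames = list(NULL, "(Intercept)")))
  if (is.null(data$site_covs))
    stop("`data` has no site covariates but `psi_formula` requires them")
  stats::model.matrix(psi_formula, data$site_covs)
}
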