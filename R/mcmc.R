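#' MCMC sampler settings
#'
#' Defaults follow the published configuration: 5 chains of 30,000
#' iterations, a burn-in of 20,000 and thinning by 3. Tests and desk-scale
#' pipelines typically pass a reduced configuration.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Keep every \code{thin}-th post-burn-in iteration.
#' @param seed Integer seed fixing all sampler randomness.
#' @return Object of class \code{mcmc_control}.
#' @export
mcmc_control <- function(n_chains = 5, n_iter = 30000, burn_in = 20000,
                         thin = 3, seed = 1) {
  stopifnot(n_chains >= 1, thin >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical split-free R-hat for one scalar parameter traced by several
#' chains: with within-chain variance W, between-chain variance B and
#' \code{var+ = (n-1)/n W + B/n}, returns \code{sqrt(var+ / W)}. Values near
#' 1 indicate the chains have mixed.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length draw
#'   vectors from at least 2 chains of at least 2 draws.
#' @return The R-hat statistic.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  if (m < 2L || n < 2L) stop("need at least 2 chains of at least 2 draws")
  W <- mean(apply(chains, 2L, stats::var))
  if (!is.finite(W) || W == 0) stop("degenerate chains: within-chain variance is zero")
  B <- n * stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Gibbs/Metropolis sampler for the multi-season occupancy model.
# Latent Z: site-by-year full-conditional Bernoulli draws. phi, gamma, p:
# conjugate Beta(1,1) updates from latent transition/detection counts.
# Year-1 occupancy coefficients: random-walk Metropolis with Normal(0, 10)
# priors, proposal scale adapted during burn-in only.
.fit_mcmc <- function(data, st, X, structure_, ctrl, call) {
  stopifnot(inherits(ctrl, "mcmc_control"))
  d <- st$d
  K <- st$K
  n <- nrow(d)
  n_years <- ncol(d)
  nb <- ncol(X)
  lay <- .par_layout(X, structure_, n_years, data)
  n_keep <- (ctrl$n_iter - ctrl$burn_in) %/% ctrl$thin
  npar <- length(lay$names)
  draws <- matrix(NA_real_, n_keep * ctrl$n_chains, npar,
                  dimnames = list(NULL, lay$names))
  psi_fs <- matrix(NA_real_, n_keep * ctrl$n_chains, n_years)
  psi_exp <- matrix(NA_real_, n_keep * ctrl$n_chains, n_years)
  occK <- matrix(NA_real_, n_keep * ctrl$n_chains, n_years)
  chain_id <- integer(n_keep * ctrl$n_chains)
  zbar <- matrix(0, n, n_years)
  accept <- 0L
  proposals <- 0L
  phi_year <- structure_$phi == "year"
  gam_year <- structure_$gamma == "year"
  p_year <- structure_$p == "year"
  row0 <- 0L
  for (ch in seq_len(ctrl$n_chains)) {
    set.seed((ctrl$seed * 131L + ch) %% 2147483647L)
    Z <- matrix(0L, n, n_years)
    Z[d > 0] <- 1L
    Z[d == 0] <- stats::rbinom(sum(d == 0), 1L, 0.5)
    beta <- stats::rnorm(nb, 0, 1)
    phi <- stats::runif(if (phi_year) n_years - 1L else 1L, 0.4, 0.9)
    gam <- stats::runif(if (gam_year) n_years - 1L else 1L, 0.02, 0.3)
    p <- stats::runif(if (p_year) n_years else 1L, 0.1, 0.6)
    prop_sd <- 0.3
    acc_win <- 0L
    keep_i <- 0L
    eta <- drop(X %*% beta)
    psi1 <- stats::plogis(eta)
    for (it in seq_len(ctrl$n_iter)) {
      phiT <- if (phi_year) phi else rep(phi, max(n_years - 1L, 1L))
      gamT <- if (gam_year) gam else rep(gam, max(n_years - 1L, 1L))
      pT <- if (p_year) p else rep(p, n_years)
      # -- latent occupancy states
      for (t in seq_len(n_years)) {
        l1 <- pT[t]^d[, t] * (1 - pT[t])^(K[, t] - d[, t])
        l0 <- as.numeric(d[, t] == 0)
        pr1 <- if (t == 1L) psi1 else {
          zp <- Z[, t - 1L]
          gamT[t - 1L] + (phiT[t - 1L] - gamT[t - 1L]) * zp
        }
        w1 <- pr1 * l1
        w0 <- (1 - pr1) * l0
        if (t < n_years) {
          nxt <- Z[, t + 1L]
          w1 <- w1 * ((1 - phiT[t]) + (2 * phiT[t] - 1) * nxt)
          w0 <- w0 * ((1 - gamT[t]) + (2 * gamT[t] - 1) * nxt)
        }
        Z[, t] <- stats::rbinom(n, 1L, w1 / pmax(w1 + w0, 1e-300))
      }
      # -- detection probability (conjugate)
      occ_cells <- colSums(K * Z)
      occ_dets <- colSums(d * Z)
      if (p_year) {
        p <- stats::rbeta(n_years, 1 + occ_dets, 1 + occ_cells - occ_dets)
      } else {
        p <- stats::rbeta(1L, 1 + sum(occ_dets), 1 + sum(occ_cells) - sum(occ_dets))
      }
      # -- survival / colonization (conjugate)
      if (n_years > 1L) {
        n1 <- colSums(Z[, -n_years, drop = FALSE])
        s1 <- colSums(Z[, -n_years, drop = FALSE] * Z[, -1L, drop = FALSE])
        n0 <- n - n1
        c0 <- colSums((1 - Z[, -n_years, drop = FALSE]) * Z[, -1L, drop = FALSE])
        if (phi_year) phi <- stats::rbeta(n_years - 1L, 1 + s1, 1 + n1 - s1)
        else phi <- stats::rbeta(1L, 1 + sum(s1), 1 + sum(n1) - sum(s1))
        if (gam_year) gam <- stats::rbeta(n_years - 1L, 1 + c0, 1 + n0 - c0)
        else gam <- stats::rbeta(1L, 1 + sum(c0), 1 + sum(n0) - sum(c0))
      }
      # -- year-1 occupancy coefficients (random-walk Metropolis)
      z1 <- Z[, 1L]
      # Bernoulli loglik in logit form: sum(z * eta - log(1 + exp(eta)))
      lp_cur <- sum(z1 * eta) - sum(log1p(exp(eta))) -
        sum(beta^2) / 200
      prop <- beta + stats::rnorm(nb, 0, prop_sd)
      eta_prop <- drop(X %*% prop)
      lp_prop <- sum(z1 * eta_prop) - sum(log1p(exp(eta_prop))) -
        sum(prop^2) / 200
      proposals <- proposals + 1L
      if (log(stats::runif(1)) < lp_prop - lp_cur) {
        beta <- prop
        eta <- eta_prop
        psi1 <- stats::plogis(eta)
        accept <- accept + 1L
        acc_win <- acc_win + 1L
      }
      if (it <= ctrl$burn_in && it %% 50L == 0L) {
        rate <- acc_win / 50
        prop_sd <- min(max(prop_sd * exp(rate - 0.35), 0.01), 5)
        acc_win <- 0L
      }
      # -- record
      if (it > ctrl$burn_in && (it - ctrl$burn_in) %% ctrl$thin == 0L) {
        keep_i <- keep_i + 1L
        r <- row0 + keep_i
        phiT <- if (phi_year) phi else rep(phi, max(n_years - 1L, 1L))
        gamT <- if (gam_year) gam else rep(gam, max(n_years - 1L, 1L))
        draws[r, ] <- c(beta, phi, gam, p)
        psi_fs[r, ] <- colMeans(Z)
        pe <- numeric(n_years)
        pe[1L] <- mean(psi1)
        if (n_years > 1L) for (t in 2:n_years)
          pe[t] <- occupancy_recursion(pe[t - 1L], phiT[t - 1L], gamT[t - 1L])
        psi_exp[r, ] <- pe
        occK[r, ] <- colSums(K * Z)
        chain_id[r] <- ch
        zbar <- zbar + Z
      }
    }
    row0 <- row0 + n_keep
  }
  zbar <- zbar / (n_keep * ctrl$n_chains)
  # convergence diagnostics per parameter and per derived annual occupancy
  rhat <- rep(NA_real_, npar + n_years)
  names(rhat) <- c(lay$names, paste0("psi_fs_", seq_len(n_years)))
  if (ctrl$n_chains >= 2L && n_keep >= 2L) {
    tr <- cbind(draws, psi_fs)
    for (j in seq_len(ncol(tr))) {
      mat <- matrix(tr[, j], n_keep, ctrl$n_chains)
      rhat[j] <- tryCatch(gelman_rubin(mat), error = function(e) NA_real_)
    }
  }
  conv_warn <- any(rhat > 1.1, na.rm = TRUE)
  med <- apply(draws, 2L, stats::median)
  up <- .unpack_natural(med, lay)
  psi_annual <- apply(psi_fs, 2L, stats::median)
  out <- list(call = call, data = data, structure = structure_, layout = lay,
              X = X, coefficients = med, draws = draws, chain = chain_id,
              psi_fs = psi_fs, psi_exp = psi_exp, occK = occK, zbar = zbar,
              params = up,
              psi_annual = psi_annual,
              psi_hpdi = t(apply(psi_fs, 2L, hpdi)),
              naive = vapply(data$y, naive_occupancy, 0),
              rhat = rhat, convergence_warning = conv_warn,
              accept_rate = accept / proposals,
              n_params = npar, mcmc = ctrl, engine = "mcmc")
  class(out) <- c("occudyn_mcmc", "occudyn")
  if (conv_warn)
    warning(sprintf("possible non-convergence: max R-hat = %.3f",
                    max(rhat, na.rm = TRUE)))
  out
}

# draws are stored with beta on the logit scale and phi/gamma/p on the
# probability scale; this unpacks one such row into named components.
.unpack_natural <- function(v, lay) {
  i <- lay$nb
  beta <- v[seq_len(lay$nb)]
  phi <- v[i + seq_len(lay$nphi)]; i <- i + lay$nphi
  gam <- v[i + seq_len(lay$ngam)]; i <- i + lay$ngam
  p <- v[i + seq_len(lay$np)]
  list(beta_psi = unname(beta), phi = unname(phi), gamma = unname(gam),
       p = unname(p))
}

#' Extract annual occupancy posterior draws
#'
#' @param fit An \code{occudyn_mcmc} fit.
#' @param type \code{"fs"} for finite-sample occupancy (the mean of the
#'   sampled latent states across sites at each draw; the default used for
#'   the community indicators) or \code{"expected"} for the parametric
#'   recursion value.
#' @return Matrix of draws (rows) by years (columns).
#' @export
occupancy_draws <- function(fit, type = c("fs", "expected")) {
  stopifnot(inherits(fit, "occudyn_mcmc"))
  type <- match.arg(type)
  if (type == "fs") fit$psi_fs else fit$psi_exp
}

#' Export posterior draws as long-format CSV
#'
#' Writes one row per (chain, iteration, parameter, value), including the
#' derived annual occupancies \code{psi_fs_t}. The companion reader rebuilds
#' the draw matrix.
#'
#' @param fit An \code{occudyn_mcmc} fit.
#' @param path Output CSV path.
#' @param header Optional named character vector of `# key: value` lines.
#' @export
export_posterior <- function(fit, path, header = NULL) {
  stopifnot(inherits(fit, "occudyn_mcmc"))
  n_years <- ncol(fit$psi_fs)
  tr <- cbind(fit$draws, stats::setNames(as.data.frame(fit$psi_fs),
                                         paste0("psi_fs_", seq_len(n_years))))
  long <- data.frame(
    chain = rep(fit$chain, times = ncol(tr)),
    iteration = rep(stats::ave(fit$chain, fit$chain, FUN = seq_along), times = ncol(tr)),
    parameter = rep(colnames(tr), each = nrow(tr)),
    value = unlist(tr, use.names = FALSE)
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname export_posterior
#' @param parameter For \code{read_posterior_draws}: which parameters to
#'   return (default all).
#' @return \code{read_posterior_draws} returns a draws matrix with a
#'   \code{chain} attribute.
#' @export
read_posterior_draws <- function(path, parameter = NULL) {
  long <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  pars <- unique(long$parameter)
  if (!is.null(parameter)) pars <- intersect(pars, parameter)
  sub <- long[long$parameter == pars[1L], ]
  out <- vapply(pars, function(pp) long$value[long$parameter == pp],
                numeric(nrow(sub)))
  colnames(out) <- pars
  attr(out, "chain") <- sub$chain
  out
}
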