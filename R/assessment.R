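#' Annual aggregated detection frequencies
#'
#' Total count of detections (cells equal to 1) per year, summed over sites
#' and periods, excluding unsampled cells. This is the statistic the
#' posterior predictive check compares between observed and replicated data.
#'
#' @param data An [occu_data] or a list of per-year detection matrices.
#' @return Integer vector, one count per year.
#' @export
annual_detection_frequencies <- function(data) {
  y <- if (inherits(data, "occu_data")) data$y else data
  vapply(y, function(m) sum(m == 1, na.rm = TRUE), 0)
}

#' Chi-square discrepancy between observed and expected annual counts
#'
#' Pearson-type discrepancy \code{sum((O - E)^2 / (E + c))} with a small
#' stabilizer \code{c} in the denominator so that rare species with
#' near-zero expected counts do not dominate.
#'
#' @param observed,expected Equal-length nonnegative vectors of annual
#'   detection counts (expected may be non-integer).
#' @param stabilizer Denominator constant, default 0.5.
#' @return The discrepancy (nonnegative; 0 iff observed equals expected).
#' @export
chi2_discrepancy <- function(observed, expected, stabilizer = 0.5) {
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(observed < 0)) stop("negative observed count")
  if (any(expected < 0)) stop("negative expected count")
  sum((observed - expected)^2 / (expected + stabilizer))
}

#' Bayesian posterior predictive check on annual detection frequencies
#'
#' For each retained posterior draw, the expected annual detection counts
#' are computed conditional on that draw's latent occupancy states (expected
#' detections over the sampled cells of occupied sites); a chi-square
#' discrepancy is evaluated against the observed counts, and against a new
#' realization of the data simulated from the same draw with the observed
#' missingness pattern. The Bayesian p-value is the fraction of draws whose
#' replicated discrepancy exceeds the observed one; values very close to 0
#' or 1 indicate lack of fit.
#'
#' @param fit An \code{occudyn_mcmc} fit.
#' @param seed Seed for the replicated realizations.
#' @param stabilizer Passed to [chi2_discrepancy].
#' @return Object of class \code{bppc_result}: list with per-draw
#'   \code{chi2_obs}, \code{chi2_new} and the scalar \code{bayesian_p}.
#' @export
bppc <- function(fit, seed = 1, stabilizer = 0.5) {
  stopifnot(inherits(fit, "occudyn_mcmc"))
  O <- annual_detection_frequencies(fit$data)
  n_years <- ncol(fit$psi_fs)
  lay <- fit$layout
  p_idx <- seq.int(lay$nb + lay$nphi + lay$ngam + 1L, ncol(fit$draws))
  pdr <- fit$draws[, p_idx, drop = FALSE]
  if (ncol(pdr) == 1L) pdr <- matrix(pdr, nrow(pdr), n_years)
  occK <- fit$occK
  E <- occK * pdr
  chi2_obs <- rowSums(sweep(E, 2L, O, function(e, o) (o - e)^2) / (E + stabilizer))
  chi2_new <- .with_seed(seed, {
    Orep <- matrix(stats::rbinom(length(occK), as.vector(occK), as.vector(pdr)),
                   nrow(occK))
    rowSums((Orep - E)^2 / (E + stabilizer))
  })
  structure(list(chi2_obs = chi2_obs, chi2_new = chi2_new,
                 bayesian_p = mean(chi2_new > chi2_obs)),
            class = "bppc_result")
}

#' @export
print.bppc_result <- function(x, ...) {
  cat(sprintf("Bayesian posterior predictive check (chi-square)\n  Bayesian p-value: %.3f over %d draws\n",
              x$bayesian_p, length(x$chi2_obs)))
  if (x$bayesian_p < 0.05 || x$bayesian_p > 0.95)
    cat("  note: value near 0 or 1 indicates lack of model fit\n")
  invisible(x)
}

#' Deviance information criterion of an MCMC occupancy fit
#'
#' \code{DIC = Dbar + pD} with the deviance \code{D(theta) = 2 * nll}
#' marginal over the latent states, \code{Dbar} the posterior mean deviance
#' and \code{pD = Dbar - D(theta_bar)} evaluated at the posterior mean of
#' the parameters.
#'
#' @param fit An \code{occudyn_mcmc} fit.
#' @param every Evaluate the deviance on every \code{every}-th retained draw
#'   (the posterior mean deviance is a Monte Carlo average; thinning it
#'   trades a little stability for speed).
#' @return The DIC with attributes \code{Dbar}, \code{pD}.
#' @export
dic <- function(fit, every = 1L) {
  stopifnot(inherits(fit, "occudyn_mcmc"))
  st <- .detection_stats(fit$data$y)
  n <- nrow(st$d)
  n_years <- ncol(st$d)
  lay <- fit$layout
  dev_of <- function(v) {
    up <- .unpack_natural(v, lay)
    psi1 <- stats::plogis(drop(fit$X %*% up$beta_psi))
    phi <- .expand_trans(up$phi, n_years)
    gam <- .expand_trans(up$gamma, n_years)
    pmat <- if (length(up$p) == 1L) matrix(up$p, n, n_years) else
      matrix(up$p, n, n_years, byrow = TRUE)
    -2 * sum(.loglik_sites(st$d, st$K, psi1, phi, gam, pmat))
  }
  idx <- seq(1L, nrow(fit$draws), by = as.integer(every))
  devs <- apply(fit$draws[idx, , drop = FALSE], 1L, dev_of)
  Dbar <- mean(devs)
  Dhat <- dev_of(colMeans(fit$draws))
  if (!is.finite(Dhat)) stop("non-finite deviance at the posterior mean")
  pD <- Dbar - Dhat
  structure(Dbar + pD, Dbar = Dbar, pD = pD)
}

#' Rank candidate models by an information criterion
#'
#' @param fits Named list of fits: \code{occudyn} ML fits (ranked by AIC) or
#'   \code{occudyn_mcmc} fits with a \code{criterion} vector of DIC values,
#'   or a named numeric vector of criterion values.
#' @param criterion Optional named numeric vector overriding the AIC (e.g.
#'   DIC values); must align with \code{fits}.
#' @param n_params Optional named vector of parameter counts for tie-breaks
#'   when \code{fits} is numeric.
#' @return Data frame sorted ascending by criterion with a \code{delta}
#'   column; ties are broken in favour of fewer parameters. The attribute
#'   \code{best} names the selected model.
#' @export
select_model <- function(fits, criterion = NULL, n_params = NULL) {
  if (is.numeric(fits)) {
    crit <- fits
    k <- if (is.null(n_params)) rep(NA_integer_, length(crit)) else n_params
    nms <- names(crit)
  } else {
    if (!length(fits)) stop("no candidate models supplied")
    crit <- if (is.null(criterion))
      vapply(fits, function(f) f$AIC, 0) else criterion
    k <- vapply(fits, function(f) f$n_params, 0L)
    nms <- names(fits)
  }
  if (!length(crit)) stop("no candidate models supplied")
  if (is.null(nms)) nms <- paste0("model", seq_along(crit))
  ord <- order(crit, k)
  out <- data.frame(model = nms[ord], criterion = crit[ord], k = k[ord],
                    delta = crit[ord] - crit[ord][1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "best") <- out$model[1L]
  out
}
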