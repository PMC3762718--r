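# S3 methods for occudyn fits (ML and MCMC).

.structure_label <- function(s) {
  psi_lab <- if (.is_intercept_only(s$psi)) "." else
    paste(attr(stats::terms(s$psi), "term.labels"), collapse = "+")
  sprintf("psi(%s) gamma(%s) phi(%s) p(%s)", psi_lab,
          if (s$gamma == "year") "year" else ".",
          if (s$phi == "year") "year" else ".",
          if (s$p == "year") "year" else ".")
}

#' @export
print.occudyn <- function(x, ...) {
  cat("Multi-season occupancy model, structure", .structure_label(x$structure), "\n")
  if (inherits(x, "occudyn_mcmc")) {
    cat(sprintf("  engine: MCMC (%d chains x %d iterations, burn-in %d, thin %d)\n",
                x$mcmc$n_chains, x$mcmc$n_iter, x$mcmc$burn_in, x$mcmc$thin))
    cat(sprintf("  max R-hat: %.3f%s\n", max(x$rhat, na.rm = TRUE),
                if (isTRUE(x$convergence_warning)) "  ** convergence warning **" else ""))
  } else {
    cat(sprintf("  engine: maximum likelihood; logLik %.3f, AIC %.2f (k = %d)\n",
                x$logLik, x$AIC, x$n_params))
    if (isTRUE(x$boundary)) cat(" ", x$boundary_message, "\n")
  }
  cat("  annual occupancy:", paste(sprintf("%.3f", x$psi_annual), collapse = ", "), "\n")
  cat("  naive occupancy: ", paste(sprintf("%.3f", x$naive), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.occudyn <- function(object, ...) object$coefficients

#' @export
logLik.occudyn <- function(object, ...) {
  if (inherits(object, "occudyn_mcmc"))
    stop("the MCMC engine does not maximize a likelihood; see dic()")
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' @export
vcov.occudyn <- function(object, ...) object$vcov

#' @export
summary.occudyn <- function(object, ...) {
  out <- list(fit = object)
  if (inherits(object, "occudyn_mcmc")) {
    qs <- t(apply(object$draws, 2L, stats::quantile, c(0.5, 0.025, 0.975)))
    hp <- t(apply(object$draws, 2L, function(v)
      if (max(v) - min(v) < 1e-12) c(v[1L], v[1L]) else hpdi(v)))
    out$table <- data.frame(median = qs[, 1L], hpdi_lo = hp[, 1L],
                            hpdi_hi = hp[, 2L],
                            rhat = object$rhat[rownames(qs)])
  } else {
    out$table <- data.frame(estimate = object$coefficients, se = object$se)
  }
  class(out) <- "summary.occudyn"
  out
}

#' @export
print.summary.occudyn <- function(x, ...) {
  print(x$fit)
  cat("\nParameters", if (x$fit$engine == "ml") "(link scale)" else
    "(beta on logit scale, probabilities natural)", ":\n")
  print(round(x$table, 4))
  invisible(x)
}

#' Predict occupancy from a fitted model
#'
#' @param object An \code{occudyn} fit.
#' @param newdata Optional data frame of site covariates; defaults to the
#'   fitted sites.
#' @param type \code{"psi1"} (year-1 occupancy per site), \code{"psi"}
#'   (per-site annual trajectory matrix) or \code{"p"} (detection
#'   probability per year).
#' @param ... Unused.
#' @export
predict.occudyn <- function(object, newdata = NULL,
                            type = c("psi1", "psi", "p"), ...) {
  type <- match.arg(type)
  if (type == "p") return(object$params$p)
  X <- if (is.null(newdata)) object$X else
    stats::model.matrix(object$structure$psi, newdata)
  psi1 <- stats::plogis(drop(X %*% object$params$beta_psi))
  if (type == "psi1") return(psi1)
  n_years <- length(object$psi_annual)
  out <- matrix(NA_real_, length(psi1), n_years)
  out[, 1L] <- psi1
  if (n_years > 1L) for (t in 2:n_years)
    out[, t] <- occupancy_recursion(out[, t - 1L], object$params$phi[t - 1L],
                                    object$params$gamma[t - 1L])
  out
}

#' Simulate replicate detection histories from a fitted model
#'
#' Draws latent states from the fitted (ML point or posterior-median)
#' parameters and observations Bernoulli(Z p), reusing the observed
#' missingness pattern, so replicates are directly comparable with the data.
#'
#' @param object An \code{occudyn} fit.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of [occu_data] replicates (length \code{nsim}).
#' @export
simulate.occudyn <- function(object, nsim = 1, seed = 1, ...) {
  psi1 <- predict(object, type = "psi1")
  n <- length(psi1)
  n_years <- length(object$psi_annual)
  phi <- object$params$phi
  gam <- object$params$gamma
  p <- object$params$p
  .with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      Z <- matrix(0L, n, n_years)
      Z[, 1L] <- stats::rbinom(n, 1L, psi1)
      if (n_years > 1L) for (t in 2:n_years)
        Z[, t] <- stats::rbinom(n, 1L, ifelse(Z[, t - 1L] == 1L, phi[t - 1L], gam[t - 1L]))
      y <- lapply(seq_len(n_years), function(t) {
        tmpl <- object$data$y[[t]]
        m <- matrix(stats::rbinom(length(tmpl), 1L, rep(Z[, t] * p[t], ncol(tmpl))),
                    n, ncol(tmpl))
        m[is.na(tmpl)] <- NA_integer_
        rownames(m) <- rownames(tmpl)
        m
      })
      occu_data(y, site_covs = object$data$site_covs,
                species_id = object$data$species_id)
    })
  })
}

#' Residuals of an occupancy fit
#'
#' Pearson-type residuals of per-site-per-year detection counts against
#' their marginal expectation under the fitted model
#' (\code{E = psi K p}, variance \code{psi K p (1 - p) + psi (1 - psi) (K p)^2}).
#'
#' @param object An \code{occudyn} fit.
#' @param ... Unused.
#' @return Sites-x-years matrix of residuals (NA where a site-year was
#'   never sampled).
#' @export
residuals.occudyn <- function(object, ...) {
  st <- .detection_stats(object$data$y)
  psi <- if (inherits(object, "occudyn_mcmc")) object$zbar else
    predict(object, type = "psi")
  p <- matrix(object$params$p, nrow(st$d), ncol(st$d), byrow = TRUE)
  E <- psi * st$K * p
  V <- psi * st$K * p * (1 - p) + psi * (1 - psi) * (st$K * p)^2
  r <- (st$d - E) / sqrt(pmax(V, 1e-12))
  r[st$K == 0] <- NA_real_
  r
}

#' Plot an annual occupancy trajectory
#'
#' Modeled occupancy as a line (with a shaded HPDI band for MCMC fits) and
#' the naive observed occupancies as points.
#'
#' @param x An \code{occudyn} fit.
#' @param ... Passed to [graphics::plot].
#' @export
plot.occudyn <- function(x, ...) {
  yrs <- seq_along(x$psi_annual)
  graphics::plot(yrs, x$psi_annual, type = "n", ylim = c(0, 1),
                 xlab = "year", ylab = "occupancy", ...)
  if (inherits(x, "occudyn_mcmc"))
    graphics::polygon(c(yrs, rev(yrs)), c(x$psi_hpdi[, 1L], rev(x$psi_hpdi[, 2L])),
                      col = grDevices::adjustcolor("grey60", 0.5), border = NA)
  graphics::lines(yrs, x$psi_annual, lwd = 2)
  graphics::points(yrs, x$naive, pch = 19)
  invisible(x)
}

#' @export
plot.wpi_series <- function(x, ...) {
  yrs <- seq_along(x$point)
  graphics::plot(yrs, x$point, type = "n",
                 ylim = range(c(x$hpdi, 1)), xlab = "year", ylab = "WPI", ...)
  graphics::polygon(c(yrs, rev(yrs)), c(x$hpdi[, 1L], rev(x$hpdi[, 2L])),
                    col = grDevices::adjustcolor("grey60", 0.5), border = NA)
  graphics::lines(yrs, x$point, lwd = 2)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
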