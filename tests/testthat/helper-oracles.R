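# Independent oracles used to freeze expected values: brute-force
# enumeration over all latent occupancy configurations, written against the
# model definition only (no forward recursion).

enum_site_likelihood <- function(histories, psi1, phi, gamma, p) {
  n_years <- length(histories)
  phi <- rep(phi, length.out = max(n_years - 1, 1))
  gamma <- rep(gamma, length.out = max(n_years - 1, 1))
  p <- rep(p, length.out = n_years)
  obs_prob <- function(h, pt, z) {
    h <- h[!is.na(h)]
    if (!length(h)) return(1)
    if (z == 0) return(as.numeric(!any(h == 1)))
    prod(ifelse(h == 1, pt, 1 - pt))
  }
  total <- 0
  for (code in 0:(2^n_years - 1)) {
    z <- as.integer(intToBits(code))[seq_len(n_years)]
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    if (n_years > 1) for (t in 2:n_years) {
      pr <- pr * if (z[t - 1] == 1) {
        if (z[t] == 1) phi[t - 1] else 1 - phi[t - 1]
      } else {
        if (z[t] == 1) gamma[t - 1] else 1 - gamma[t - 1]
      }
    }
    for (t in seq_len(n_years)) pr <- pr * obs_prob(histories[[t]], p[t], z[t])
    total <- total + pr
  }
  total
}

# all complete (NA-free) detection histories for one site: list of
# year-histories, iterating over every 0/1 assignment of the cells
all_histories <- function(n_years, n_periods) {
  n_cells <- n_years * n_periods
  lapply(0:(2^n_cells - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_cells)]
    split(bits, rep(seq_len(n_years), each = n_periods))
  })
}

rand_param_set <- function(n_years) {
  list(psi1 = runif(1, 0.05, 0.95),
       phi = runif(max(n_years - 1, 1), 0.05, 0.95),
       gamma = runif(max(n_years - 1, 1), 0.05, 0.95),
       p = runif(n_years, 0.05, 0.95))
}

rand_history <- function(n_years, n_periods, na_prob = 0.2) {
  lapply(seq_len(n_years), function(t) {
    h <- sample(c(0L, 1L), n_periods, replace = TRUE)
    h[runif(n_periods) < na_prob] <- NA_integer_
    h
  })
}

# shortest-window HPDI by exhaustive scan over all candidate windows,
# independent of the packaged implementation
hpdi_scan <- function(draws, level = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(Inf, NA, NA)
  for (i in 1:(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + m - 1])
  }
  best[2:3]
}

# drop everything but dim so matrices compare on cell content alone
strip_attrs <- function(m) {
  structure(as.vector(m), dim = dim(m))
}
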