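# shared fixtures and independent oracles

# brute-force stress autocorrelation (direct time average at every lag)
brute_force_g <- function(stress, volume, kBT, lags_idx) {
  x <- as.matrix(stress[, c("sxy", "sxz", "syz")])
  n <- nrow(x)
  vapply(lags_idx, function(j) {
    cnt <- n - j
    volume / (3 * kBT) * sum(x[seq_len(cnt), ] * x[seq_len(cnt) + j, ]) / cnt
  }, numeric(1))
}

# synthetic exponential (Maxwell) correlation object on a log-spaced grid
maxwell_corr <- function(G0, tau, tmax = 12 * tau, n = 300,
                         tmin = tau / 2000) {
  lag <- c(0, exp(seq(log(tmin), log(tmax), length.out = n)))
  structure(
    tibble::tibble(lag = lag, G = G0 * exp(-lag / tau),
                   count = 1000, level = 0),
    volume = 1, kBT = 1,
    class = c("stress_correlation", class(tibble::tibble()))
  )
}

# closed-form bond-length density ~ r^2 exp(-U(r)/kBT) for FENE + WCA
bond_boltzmann_cdf <- function(r_grid, k = 30, R0 = 1.5, eps = 1,
                               sigma = 1, kBT = 1) {
  u <- function(r) {
    ufene <- -0.5 * k * R0^2 * log(1 - (r / R0)^2)
    rc <- 2^(1 / 6) * sigma
    uwca <- ifelse(r < rc,
                   4 * eps * ((sigma / r)^12 - (sigma / r)^6) + eps, 0)
    ufene + uwca
  }
  rr <- seq(1e-4, R0 - 1e-6, length.out = 4000)
  dens <- rr^2 * exp(-(u(rr) - min(u(rr))) / kBT)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(rr, cdf, xout = r_grid, rule = 2)$y
}

# Ornstein-Uhlenbeck series with unit stationary variance
ou_series <- function(n, tau, dt, seed) {
  set.seed(seed)
  a <- exp(-dt / tau)
  s <- sqrt(1 - a^2)
  as.numeric(stats::filter(c(rnorm(1), s * rnorm(n - 1)), a,
                           method = "recursive"))
}

# tiny passive melt, pushed off (reused across tests)
tiny_melt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_params(N = 4, Np = 8, Pe = 0, seed = 11)
      cfg <- soft_pushoff(build_random_melt(p, seed = 11), p, seed = 11)
      cache <<- list(params = p, config = cfg)
    }
    cache
  }
})
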