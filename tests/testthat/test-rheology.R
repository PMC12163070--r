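make_stress <- function(sxy, sxz = 0 * sxy, syz = 0 * sxy, dt = 0.01,
                        volume = 100) {
  n <- length(sxy)
  tibble::tibble(time = (seq_len(n) - 1) * dt,
                 sxx = 0, syy = 0, szz = 0,
                 sxy = sxy, sxz = sxz, syz = syz, volume = volume)
}

test_that("the correlator reproduces constant and white-noise limits", {
  # constant stress sxy = c: G(t) = V c^2 / (3 kBT) at every lag
  st <- make_stress(rep(0.5, 2000), volume = 100)
  g <- accumulate_g(st, kBT = 2)
  expect_true(all(abs(g$G - 100 * 0.25 / 6) < 1e-12))

  # white noise of variance s^2 in all three components:
  # G(0) = V s^2 / kBT, G(t>0) compatible with zero
  set.seed(1)
  n <- 60000
  s <- 0.3
  st <- make_stress(rnorm(n, 0, s), rnorm(n, 0, s), rnorm(n, 0, s),
                    volume = 50)
  g <- accumulate_g(st, kBT = 1)
  expect_equal(g$G[g$lag == 0], 50 * s^2, tolerance = 0.02)
  later <- g$G[g$lag > 0]
  expect_lt(max(abs(later)) / (50 * s^2), 0.05)

  expect_error(accumulate_g(make_stress(1)), "insufficient")
  expect_error(accumulate_g(make_stress(c(1, 2, 3),
                                        dt = 0.01)[c(1, 2, 3), ][
                                          c(1, 3, 2), ]), "uniform")
})

test_that("multiple-tau estimates match the brute-force correlator", {
  set.seed(42)
  n <- 10000
  x <- ou_series(n, tau = 0.5, dt = 0.01, seed = 42)
  y <- ou_series(n, tau = 0.5, dt = 0.01, seed = 43)
  z <- ou_series(n, tau = 0.5, dt = 0.01, seed = 44)
  st <- make_stress(x, y, z, dt = 0.01, volume = 10)
  g <- accumulate_g(st, kBT = 1)
  idx <- g$count >= 100 & g$lag > 0
  lags_idx <- as.integer(round(g$lag[idx] / 0.01))
  bf <- brute_force_g(st, 10, 1, lags_idx)
  # relative deviation < 2% of G(0) at every well-sampled lag
  expect_lt(max(abs(g$G[idx] - bf)) / g$G[g$lag == 0], 0.02)
})

test_that("an OU stress series yields its known correlation time", {
  # ~1e4 correlation times per component keep the fit's statistical
  # error well inside the 5% tolerance
  tau <- 0.5
  st <- make_stress(ou_series(1e6, tau, 0.005, seed = 7),
                    ou_series(1e6, tau, 0.005, seed = 8),
                    ou_series(1e6, tau, 0.005, seed = 9),
                    dt = 0.005, volume = 1)
  g <- accumulate_g(st)
  fit <- fit_plateau_and_tau(g)
  expect_equal(fit$tau_eff, tau, tolerance = 0.05)
})

test_that("the terminal fit recovers an exact Maxwell model to 1e-6", {
  corr <- maxwell_corr(G0 = 2, tau = 5)
  fit <- fit_plateau_and_tau(corr)
  expect_equal(fit$G0, 2, tolerance = 1e-6)
  expect_equal(fit$tau_eff, 5, tolerance = 1e-6)
  expect_false(fit$no_plateau)
  expect_true(fit$plateau_detected)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "G0"], 2, tolerance = 1e-6)
  expect_gte(glance(fit)$r.squared, 0.999)
})

test_that("a pure power law raises the Rouse-like no-plateau flag", {
  lag <- c(0, exp(seq(log(0.01), log(400), length.out = 200)))
  corr <- tibble::tibble(lag = lag, G = c(12, lag[-1]^(-0.5)), count = 500)
  fit <- fit_plateau_and_tau(corr)
  expect_true(fit$no_plateau)
  expect_false(fit$plateau_detected)
  expect_equal(fit$mid_slope, -0.5, tolerance = 0.05)
})

test_that("Maxwell parameters survive multiplicative noise and scale grids", {
  # 5% noise: both parameters within 3%
  set.seed(3)
  corr <- maxwell_corr(G0 = 2, tau = 5)
  corr$G <- corr$G * exp(rnorm(nrow(corr), 0, 0.05))
  fit <- fit_plateau_and_tau(corr)
  expect_equal(fit$G0, 2, tolerance = 0.03)
  expect_equal(fit$tau_eff, 5, tolerance = 0.03)

  # parameter recovery across 3 decades of G0 and tau at 5% noise
  set.seed(4)
  for (G0 in c(0.05, 1, 50)) {
    for (tau in c(0.2, 5, 200)) {
      corr <- maxwell_corr(G0 = G0, tau = tau)
      corr$G <- corr$G * exp(rnorm(nrow(corr), 0, 0.05))
      fit <- fit_plateau_and_tau(corr)
      expect_equal(fit$G0, G0, tolerance = 0.03)
      expect_equal(fit$tau_eff, tau, tolerance = 0.03)
    }
  }
})

test_that("Green-Kubo integration matches closed forms", {
  # trapezoid on {2,2,2} at t = {0,1,2}: eta(2) = 4
  corr <- tibble::tibble(lag = c(0, 1, 2), G = c(2, 2, 2), count = 10)
  eta <- green_kubo_eta(corr)
  expect_equal(eta$eta[3], 4)

  # Maxwell integrated far past tau: eta_inf = G0 tau
  corr <- maxwell_corr(G0 = 2, tau = 5, tmax = 2500, n = 3000)
  eta <- green_kubo_eta(corr)
  expect_equal(eta_inf(eta), 10, tolerance = 1e-3)
  expect_true(attr(eta, "saturated"))

  # zero modulus: zero viscosity
  corr0 <- tibble::tibble(lag = c(0, 1, 2, 4), G = rep(0, 4), count = 10)
  expect_true(all(green_kubo_eta(corr0)$eta == 0))
})

test_that("moduli match the Maxwell closed forms and locate omega_c", {
  G0 <- 2
  tau <- 5
  corr <- maxwell_corr(G0 = G0, tau = tau, tmax = 200, n = 4000,
                       tmin = 1e-4)
  m <- moduli(corr)
  w <- m$omega
  Gp_ref <- G0 * w^2 * tau^2 / (1 + w^2 * tau^2)
  Gpp_ref <- G0 * w * tau / (1 + w^2 * tau^2)
  mid <- w > 2e-2 & w < 50   # away from truncation-dominated extremes
  expect_lt(max(abs(m$Gp[mid] - Gp_ref[mid]) / Gp_ref[mid]), 0.005)
  expect_lt(max(abs(m$Gpp[mid] - Gpp_ref[mid]) / Gpp_ref[mid]), 0.005)
  expect_equal(omega_c(m), 1 / tau, tolerance = 0.005)

  # low-frequency limit: G''/omega -> G0 tau = eta_inf
  wlo <- which(w < 2e-2)
  expect_equal(m$Gpp[wlo[1]] / w[wlo[1]], G0 * tau, tolerance = 0.01)

  # zero modulus: both moduli vanish, no crossing
  z <- moduli(tibble::tibble(lag = c(0, 1, 2, 8), G = rep(0, 4),
                             count = 1))
  expect_true(all(z$Gp == 0) && all(z$Gpp == 0))
  expect_true(is.na(omega_c(z)))
})

test_that("the two time extractors are consistent: omega_c * tau_eff ~ 1", {
  for (tau in c(0.5, 5, 80)) {
    corr <- maxwell_corr(G0 = 1.3, tau = tau, tmax = 40 * tau, n = 2500,
                         tmin = tau / 1e4)
    fit <- fit_plateau_and_tau(corr)
    wc <- omega_c(moduli(corr))
    expect_gt(wc * fit$tau_eff, 0.8)
    expect_lt(wc * fit$tau_eff, 1.2)
  }
})

test_that("the disengagement-time interpolation obeys its closed forms", {
  expect_equal(tau_eff_prediction(100, 8), 1 / (1e-6 + 0.08))
  expect_equal(tau_eff_prediction(100, 8), 12.4998, tolerance = 1e-4)
  expect_equal(tau_eff_prediction(100, 0), 1e6)
  # active branch dominates at large L: tau_eff -> L/v
  expect_equal(tau_eff_prediction(1e5, 2) / (1e5 / 2), 1, tolerance = 1e-4)
  expect_error(tau_eff_prediction(-1, 8))
})

test_that("activity rescaling collapses curves built on the scaling laws", {
  # point mapping: G = 8 at t = 1, Fp = 8, L = 100, v = 8 -> (0.08, 0.01)
  one <- tibble::tibble(id = 1, t = 1, value = 8, L = 100, v = 8, Fp = 8)
  rc <- rescale_collapse(one, "stress")
  expect_equal(rc$curves$x, 0.08)
  expect_equal(rc$curves$y, 0.01)

  # identical curves: zero score
  xs <- exp(seq(log(0.01), log(10), length.out = 50))
  two <- dplyr::bind_rows(
    tibble::tibble(id = 1, t = xs, value = 3 * exp(-xs), L = 1, v = 1,
                   Fp = 1),
    tibble::tibble(id = 2, t = xs, value = 3 * exp(-xs), L = 1, v = 1,
                   Fp = 1))
  expect_equal(rescale_collapse(two, "stress")$score, 0)

  # Maxwell family with G0 ~ Fp*L and tau ~ L/v collapses exactly
  xgrid <- exp(seq(log(0.005), log(6), length.out = 80))
  fam <- dplyr::bind_rows(lapply(1:3, function(k) {
    L <- c(100, 400, 1600)[k]
    Fp <- c(2, 8, 16)[k]
    v <- Fp
    tt <- xgrid * L / v
    tibble::tibble(id = k, t = tt, value = 0.7 * Fp * L * exp(-tt * v / L),
                   L = L, v = v, Fp = Fp)
  }))
  expect_lt(rescale_collapse(fam, "stress")$score, 1e-6)

  # viscosity mode: eta ~ zeta L^2 f(tv/L) collapses too
  fam_eta <- dplyr::bind_rows(lapply(1:2, function(k) {
    L <- c(100, 900)[k]
    v <- 4
    tt <- xgrid * L / v
    tibble::tibble(id = k, t = tt, value = L^2 * (1 - exp(-tt * v / L)),
                   L = L, v = v, zeta = 1)
  }))
  expect_lt(rescale_collapse(fam_eta, "viscosity")$score, 1e-6)

  expect_error(rescale_collapse(one[, -6], "stress"), "missing")
})

test_that("steady-state diagnostics pass and fail as constructed", {
  set.seed(11)
  n <- 4000
  iso <- tibble::tibble(time = seq_len(n) * 0.01,
                        sxx = rnorm(n), syy = rnorm(n), szz = rnorm(n),
                        sxy = rnorm(n), sxz = rnorm(n), syz = rnorm(n),
                        volume = 100)
  rep <- steady_state_diagnostics(iso)
  expect_true(rep$pass[rep$check == "isotropy"])
  expect_true(rep$pass[rep$check == "stationarity_pressure"])

  # constructed anisotropy sxx = 2 syy: isotropy must fail
  bad <- iso
  bad$sxx <- 2 + rnorm(n, 0, 0.01)
  bad$syy <- 1 + rnorm(n, 0, 0.01)
  repb <- steady_state_diagnostics(bad)
  expect_false(repb$pass[repb$check == "isotropy"])

  # time-shuffling preserves marginals: stationarity still passes
  shuf <- iso[sample.int(n), ]
  shuf$time <- iso$time
  reps <- steady_state_diagnostics(shuf)
  expect_true(reps$pass[reps$check == "stationarity_pressure"])

  # a full passive run: all three checks evaluated, isotropy passes
  tm <- tiny_melt()
  sched <- run_schedule(4000, stride_stress = 10, stride_log = 200,
                        stride_config = 2000, steady_state_time = 0)
  run <- bd_run(tm$config, tm$params, sched, seed = 12)
  repr <- steady_state_diagnostics(run)
  expect_true(all(c("isotropy", "stationarity_Ree2",
                    "velocity_correlation_decay") %in% repr$check))
  expect_true(repr$pass[repr$check == "isotropy"])
  expect_true(repr$pass[repr$check == "velocity_correlation_decay"])
})
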