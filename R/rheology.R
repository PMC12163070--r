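#' Stress autocorrelation via a multiple-tau correlator
#'
#' Estimates the stress relaxation modulus
#' `G(t) = V/(3 kBT) * sum_{ab in xy,xz,yz} <sigma_ab(t) sigma_ab(0)>`
#' from steady-state stress samples on a uniform grid, using a
#' multiple-tau (logarithmic-lag) correlator: within each level all lags
#' up to the block size are correlated directly, then the series is
#' coarse-grained by pairwise pre-averaging and the next level covers
#' lags twice as far. On short series the estimator agrees with the
#' brute-force time average up to the pre-averaging error.
#'
#' @param stress Tibble of steady-state samples with columns `time`,
#'   `sxy`, `sxz`, `syz` (and optionally `volume`), uniformly spaced.
#' @param volume Simulation box volume (sigma^3); defaults to the
#'   `volume` column.
#' @param kBT Thermal energy.
#' @param block Lags correlated directly per level (power of two).
#' @return Tibble of class `stress_correlation` with `lag` (tau0), `G`
#'   (kBT/sigma^3), `count` (sample pairs per lag) and `level`;
#'   attributes `volume`, `kBT`.
#' @export
accumulate_g <- function(stress, volume = NULL, kBT = 1, block = 16) {
  if (nrow(stress) < 2) {
    stop("insufficient data: need at least 2 stress samples")
  }
  volume <- volume %||% stress$volume[1]
  if (is.null(volume) || is.na(volume)) stop("volume must be supplied")
  dts <- diff(stress$time)
  dt0 <- stats::median(dts)
  if (any(abs(dts - dt0) > 1e-6 * max(dt0, 1e-300))) {
    stop("stress samples must be uniformly spaced in time")
  }
  x <- as.matrix(stress[, c("sxy", "sxz", "syz")])
  pref <- volume / (3 * kBT)
  rows <- list()
  level <- 0L
  spacing <- dt0
  repeat {
    n <- nrow(x)
    if (n < 2) break
    jmax <- min(block - 1L, n - 1L)
    jmin <- if (level == 0L) 0L else block %/% 2L
    if (jmin > jmax) break
    for (j in jmin:jmax) {
      cnt <- n - j
      s <- sum(x[seq_len(cnt), ] * x[seq_len(cnt) + j, ])
      rows[[length(rows) + 1L]] <-
        c(lag = j * spacing, G = pref * s / cnt, count = cnt,
          level = level)
    }
    if (n < 2L * block) break
    m <- floor(n / 2) * 2
    x <- (x[seq(1, m, by = 2), , drop = FALSE] +
            x[seq(2, m, by = 2), , drop = FALSE]) / 2
    spacing <- spacing * 2
    level <- level + 1L
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::arrange(out, .data$lag)
  structure(out, volume = volume, kBT = kBT, dt0 = dt0,
            class = c("stress_correlation", class(out)))
}

#' Plateau modulus and disengagement time from G(t)
#'
#' Fits the terminal exponential decay `G(t) = G0 exp(-t/tau_eff)` by
#' least squares on `log G(t)`, auto-selecting the window: among all
#' candidate windows that start where `G` has already decayed below 80%
#' of its running maximum, extend down to 5% of the window-start value,
#' contain at least 5 points and fit with `R^2 >= r2_min`, the one with
#' the largest time span wins. The mid-time log-log slope of `G` (over
#' times well before the terminal window) classifies the relaxation: a
#' slope steeper than `slope_flag` is Rouse-like and sets the no-plateau
#' flag, as does failure to find any exponential window.
#'
#' @param corr A [accumulate_g()] result (or any tibble with `lag`, `G`).
#' @param ratio_lo Lower decay ratio bounding the fit window.
#' @param r2_min Minimum R^2 for an acceptable window.
#' @param slope_flag Mid-time log-log slope below which the no-plateau
#'   (Rouse-like) flag is raised.
#' @return An object of class `plateau_fit` with elements `G0` (the fit
#'   amplitude, the primary estimate), `G0_plateau` (a direct plateau
#'   reading: the median of `G` over the mid window), `tau_eff`,
#'   `window`, `r2`, `mid_slope`, `mid_window`, `no_plateau`,
#'   `plateau_detected`. [tidy()] and [glance()] methods are provided.
#' @export
fit_plateau_and_tau <- function(corr, ratio_lo = 0.05, r2_min = 0.98,
                                slope_flag = -0.35) {
  d <- corr[corr$lag > 0 & is.finite(corr$G), , drop = FALSE]
  t <- d$lag
  g <- d$G
  n <- length(t)
  gmax_run <- cummax(ifelse(is.finite(g), g, -Inf))
  best <- NULL
  cand <- list()
  for (s in seq_len(max(0, n - 4))) {
    if (!is.finite(g[s]) || g[s] <= 0) next
    if (g[s] > 0.8 * gmax_run[s]) next   # still on/above the plateau
    ref <- g[s]
    e <- s
    while (e + 1 <= n && is.finite(g[e + 1]) && g[e + 1] > 0 &&
           g[e + 1] >= ratio_lo * ref) {
      e <- e + 1
    }
    if (e - s + 1 < 5) next
    if (g[e] > 0.8 * ref) next           # no actual decay inside window
    tt <- t[s:e]
    lg <- log(g[s:e])
    # weights between uniform (multiplicative noise) and count*G^2
    # (additive correlator noise): count * G downweights the noisy tail
    # without discarding the well-decayed decades
    wts <- d$count[s:e] * g[s:e]
    wts <- wts / mean(wts)
    fit <- stats::lm.wfit(cbind(1, tt), lg, wts)
    res <- fit$residuals
    r2 <- 1 - sum(wts * res^2) /
      sum(wts * (lg - sum(wts * lg) / sum(wts))^2)
    if (!is.finite(r2) || r2 < r2_min) next
    span <- tt[length(tt)] - tt[1]
    cand[[length(cand) + 1L]] <- list(span = span, s = s, e = e,
                                      G0 = exp(fit$coefficients[1]),
                                      tau = -1 / fit$coefficients[2],
                                      r2 = r2)
  }
  if (length(cand) > 0) {
    spans <- vapply(cand, function(cc) cc$span, numeric(1))
    # among near-maximal spans, prefer the earliest start: it minimises
    # the extrapolation lever of the intercept (= G0)
    ok <- which(spans >= 0.9 * max(spans))
    best <- cand[[ok[which.min(vapply(cand[ok], function(cc) cc$s,
                                      numeric(1)))]]]
    # refine in linear space (free of the log-transform's small-G bias),
    # weighting between the additive and multiplicative noise models
    tt <- t[best$s:best$e]
    gg <- g[best$s:best$e]
    cc <- d$count[best$s:best$e]
    theta <- c(log(best$G0), 1 / best$tau)
    for (it in 1:25) {
      mu <- exp(theta[1] - theta[2] * tt)
      w <- cc / pmax(mu, 1e-300)
      r <- gg - mu
      J <- cbind(mu, -tt * mu)
      A <- crossprod(J, w * J)
      bvec <- crossprod(J, w * r)
      step <- tryCatch(solve(A, bvec), error = function(e) NULL)
      if (is.null(step)) break
      theta <- theta + as.vector(step)
      if (max(abs(step)) < 1e-12) break
    }
    if (is.finite(theta[1]) && is.finite(theta[2]) && theta[2] > 0) {
      best$G0 <- exp(theta[1])
      best$tau <- 1 / theta[2]
    }
  }
  pos <- which(g > 0)
  mid_slope <- NA_real_
  mid_window <- c(NA_real_, NA_real_)
  mid_from <- function(lo, hi) {
    idx <- pos[t[pos] >= lo & t[pos] <= hi]
    if (length(idx) < 3) return(NULL)
    f <- stats::lm.fit(cbind(1, log(t[idx])), log(g[idx]))
    list(slope = unname(f$coefficients[2]), window = c(lo, hi))
  }
  ms <- NULL
  if (!is.null(best)) {
    tw <- t[best$s]
    ms <- mid_from(tw / 30, tw / 3) %||% mid_from(tw / 100, tw / 2)
  }
  if (is.null(ms) && length(pos) >= 3) {
    # no terminal fit to anchor on: take the mid-decay window, where G has
    # fallen to between 50% and 5% of its first-lag value (anchored to the
    # signal's own decay, not to the extent of the noisy tail)
    gref <- g[pos[1]]
    idx <- pos[g[pos] <= 0.5 * gref & g[pos] >= 0.05 * gref]
    if (length(idx) >= 3) {
      ms <- mid_from(min(t[idx]), max(t[idx]))
    }
  }
  if (is.null(ms) && length(pos) >= 3) {
    lr <- range(log(t[pos]))
    ms <- mid_from(exp(lr[1] + diff(lr) / 3), exp(lr[1] + 2 * diff(lr) / 3))
  }
  if (!is.null(ms)) {
    mid_slope <- ms$slope
    mid_window <- ms$window
  }
  no_plateau <- is.null(best) ||
    (is.finite(mid_slope) && mid_slope < slope_flag)
  # secondary "plateau reading": the median of G over the mid window
  G0_plateau <- if (all(is.finite(mid_window))) {
    idx <- pos[t[pos] >= mid_window[1] & t[pos] <= mid_window[2]]
    if (length(idx) >= 1) stats::median(g[idx]) else NA_real_
  } else {
    NA_real_
  }
  structure(list(
    G0 = if (is.null(best)) NA_real_ else unname(best$G0),
    G0_plateau = G0_plateau,
    tau_eff = if (is.null(best)) NA_real_ else unname(best$tau),
    window = if (is.null(best)) c(NA_real_, NA_real_)
             else c(t[best$s], t[best$e]),
    r2 = if (is.null(best)) NA_real_ else best$r2,
    mid_slope = mid_slope, mid_window = mid_window,
    no_plateau = no_plateau,
    plateau_detected = !no_plateau && !is.null(best)
  ), class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  if (x$no_plateau) {
    cat("<plateau_fit> no plateau (Rouse-like); mid-time log-log slope ",
        signif(x$mid_slope, 3), "\n", sep = "")
  } else {
    cat("<plateau_fit> G0 = ", signif(x$G0, 5), " kBT/sigma^3, tau_eff = ",
        signif(x$tau_eff, 5), " tau0 (window ",
        signif(x$window[1], 3), "..", signif(x$window[2], 3),
        " tau0, R^2 = ", signif(x$r2, 4), ")\n", sep = "")
  }
  invisible(x)
}

#' @method tidy plateau_fit
#' @export
tidy.plateau_fit <- function(x, ...) {
  tibble::tibble(term = c("G0", "tau_eff"),
                 estimate = c(x$G0, x$tau_eff))
}

#' @method glance plateau_fit
#' @export
glance.plateau_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, G0_plateau = x$G0_plateau,
                 window_start = x$window[1],
                 window_end = x$window[2], mid_slope = x$mid_slope,
                 no_plateau = x$no_plateau,
                 plateau_detected = x$plateau_detected)
}

#' Green-Kubo time-dependent viscosity
#'
#' `eta(t) = integral_0^t G(t') dt'` by cumulative trapezoidal quadrature
#' on the (non-uniform, multiple-tau) lag grid; the long-time viscosity
#' `eta_inf` is estimated as the mean of `eta(t)` over the final decade of
#' lags, with a saturation diagnostic.
#'
#' @param corr A [accumulate_g()] result.
#' @return Tibble of class `viscosity_curve` with `t`, `eta`
#'   (kBT tau0/sigma^3), attributes `eta_inf` and `saturated` (logical:
#'   did `eta` change by < 5% over the final decade).
#' @export
green_kubo_eta <- function(corr) {
  t <- corr$lag
  g <- corr$G
  eta <- pracma::cumtrapz(t, g)[, 1]
  fin <- t >= max(t) / 10
  eta_inf <- mean(eta[fin])
  sat <- diff(range(eta[fin])) <= 0.05 * max(abs(eta_inf), 1e-300)
  structure(tibble::tibble(t = t, eta = eta),
            eta_inf = eta_inf, saturated = sat,
            class = c("viscosity_curve", class(tibble::tibble())))
}

#' Long-time viscosity from a viscosity curve
#' @param eta_curve A [green_kubo_eta()] result.
#' @return `eta_inf` (kBT tau0/sigma^3).
#' @export
eta_inf <- function(eta_curve) attr(eta_curve, "eta_inf")

#' Storage and loss moduli from G(t)
#'
#' One-sided Fourier transform of the relaxation modulus,
#' `G'(w) = w * int G(t) sin(wt) dt` and `G''(w) = w * int G(t) cos(wt) dt`,
#' evaluated by exact piecewise-linear (Filon-type) quadrature on the
#' non-uniform lag grid, which stays accurate when `w dt >> 1`. The
#' crossover frequency `omega_c` is located by log-log interpolation of
#' the `G' = G''` crossing.
#'
#' @param corr A [accumulate_g()] result; `G` should have decayed to
#'   below 1% of `G(0)` within the data span (otherwise a warning is
#'   given and the truncated transform returned).
#' @param omega Frequency grid (1/tau0); defaults to a log grid spanning
#'   `1/t_max .. 1/t_min`.
#' @return Tibble of class `dynamic_moduli` with `omega`, `Gp`, `Gpp`,
#'   attribute `omega_c` (NA when no crossing lies in range).
#' @export
moduli <- function(corr, omega = NULL) {
  t <- corr$lag
  g <- corr$G
  keep <- is.finite(g)
  t <- t[keep]
  g <- g[keep]
  if (g[length(g)] > 0.01 * max(g)) {
    warning("G(t) has not decayed below 1% of its maximum within the ",
            "data span; moduli are truncated transforms")
  }
  tpos <- t[t > 0]
  omega <- omega %||% exp(seq(log(1 / max(t)), log(1 / min(tpos)),
                              length.out = 200))
  S <- numeric(length(omega))
  C <- numeric(length(omega))
  for (k in seq_len(length(t) - 1)) {
    t1 <- t[k]; t2 <- t[k + 1]
    h <- t2 - t1
    if (h <= 0) next
    b <- (g[k + 1] - g[k]) / h
    a <- g[k] - b * t1
    small <- omega * h < 1e-3
    w <- omega
    # exact piecewise-linear transforms
    sin_ex <- (-(a + b * t2) * cos(w * t2) + (a + b * t1) * cos(w * t1)) / w +
      b * (sin(w * t2) - sin(w * t1)) / w^2
    cos_ex <- ((a + b * t2) * sin(w * t2) - (a + b * t1) * sin(w * t1)) / w +
      b * (cos(w * t2) - cos(w * t1)) / w^2
    # Simpson fallback where w*h is tiny (avoids cancellation)
    tm <- (t1 + t2) / 2
    gm <- a + b * tm
    sin_s <- h / 6 * (g[k] * sin(w * t1) + 4 * gm * sin(w * tm) +
                        g[k + 1] * sin(w * t2))
    cos_s <- h / 6 * (g[k] * cos(w * t1) + 4 * gm * cos(w * tm) +
                        g[k + 1] * cos(w * t2))
    S <- S + ifelse(small, sin_s, sin_ex)
    C <- C + ifelse(small, cos_s, cos_ex)
  }
  Gp <- omega * S
  Gpp <- omega * C
  omega_c <- NA_real_
  ok <- Gp > 0 & Gpp > 0
  if (any(ok)) {
    dlg <- log(Gp[ok]) - log(Gpp[ok])
    wo <- omega[ok]
    sc <- which(diff(sign(dlg)) != 0)
    if (length(sc) > 0) {
      i <- sc[1]
      f <- dlg[i] / (dlg[i] - dlg[i + 1])
      omega_c <- exp(log(wo[i]) + f * (log(wo[i + 1]) - log(wo[i])))
    }
  }
  structure(tibble::tibble(omega = omega, Gp = Gp, Gpp = Gpp),
            omega_c = omega_c,
            class = c("dynamic_moduli", class(tibble::tibble())))
}

#' Crossover frequency of the dynamic moduli
#' @param mod A [moduli()] result.
#' @return `omega_c` (1/tau0), or `NA` if `G'` and `G''` do not cross.
#' @export
omega_c <- function(mod) attr(mod, "omega_c")

#' Interpolated disengagement-time estimate
#'
#' `tau_eff = 1 / (D0 sigma / L^3 + v / L)`: the passive branch is
#' reptative (`~ L^3/(D0 sigma)`), the active branch is the time `L/v`
#' for a chain to crawl its own contour length; the faster mechanism
#' dominates.
#'
#' @param L Contour length (sigma).
#' @param v Self-propulsion speed (sigma/tau0).
#' @param D0 Monomer diffusivity.
#' @param sigma Bead diameter.
#' @return `tau_eff` (tau0).
#' @examples
#' tau_eff_prediction(100, 8)   # ~12.5 tau0
#' tau_eff_prediction(100, 0)   # 1e6 tau0 (passive branch)
#' @export
tau_eff_prediction <- function(L, v, D0 = 1, sigma = 1) {
  if (any(L <= 0)) stop("L must be positive")
  if (any(v < 0)) stop("v must be non-negative")
  1 / (D0 * sigma / L^3 + v / L)
}

#' Rescale curves onto the activity master form
#'
#' Applies the activity scaling to a family of curves: in `stress` mode
#' `(t, G) -> (t v / L, G sigma^3 / (Fp L))` (the plateau scales with the
#' active energy `Fp L` and the terminal time with `L/v`); in `viscosity`
#' mode `(t, eta) -> (t v / L, eta sigma^3 / (zeta L^2))`. A collapse
#' quality score is returned: the median pairwise absolute log-distance
#' between the rescaled curves interpolated onto a common log grid.
#'
#' @param curves Tibble with columns `id`, `t`, `value` and per-curve
#'   metadata columns `L`, `v`, plus `Fp` (stress mode) or `zeta`
#'   (viscosity mode; defaults to 1 if absent).
#' @param mode `"stress"` or `"viscosity"`.
#' @param sigma Bead diameter.
#' @param n_grid Points in the common grid.
#' @return List of class `collapse` with `curves` (tibble `id, x, y`) and
#'   `score`.
#' @export
rescale_collapse <- function(curves, mode = c("stress", "viscosity"),
                             sigma = 1, n_grid = 64) {
  mode <- match.arg(mode)
  need <- c("id", "t", "value", "L", "v")
  if (mode == "stress") need <- c(need, "Fp")
  missing_cols <- setdiff(need, names(curves))
  if (length(missing_cols) > 0) {
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  }
  if (mode == "viscosity" && !"zeta" %in% names(curves)) curves$zeta <- 1
  out <- dplyr::mutate(
    curves,
    x = .data$t * .data$v / .data$L,
    y = if (mode == "stress") {
      .data$value * sigma^3 / (.data$Fp * .data$L)
    } else {
      .data$value * sigma^3 / (.data$zeta * .data$L^2)
    }
  )
  out <- out[, c("id", "x", "y")]
  score <- collapse_score(out, n_grid)
  structure(list(curves = tibble::as_tibble(out), score = score),
            class = "collapse")
}

collapse_score <- function(curves, n_grid = 64) {
  parts <- split(curves, curves$id)
  if (length(parts) < 2) return(0)
  pos <- lapply(parts, function(p) p[p$x > 0 & p$y > 0, , drop = FALSE])
  lo <- max(vapply(pos, function(p) min(p$x), numeric(1)))
  hi <- min(vapply(pos, function(p) max(p$x), numeric(1)))
  if (!(hi > lo)) return(NA_real_)
  grid <- seq(log(lo), log(hi), length.out = n_grid)
  ly <- vapply(pos, function(p) {
    stats::approx(log(p$x), log(p$y), xout = grid, rule = 2)$y
  }, numeric(n_grid))
  k <- ncol(ly)
  dists <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dists <- c(dists, abs(ly[, i] - ly[, j]))
    }
  }
  stats::median(dists)
}

#' Steady-state validity diagnostics for Green-Kubo sampling
#'
#' Checks the conditions under which the stress-autocorrelation formalism
#' is applied to an active run: (i) stationarity of the mean squared
#' end-to-end distance and of the pressure (first-half vs second-half
#' means within 3 combined standard errors), (ii) isotropy of the diagonal
#' stress components, and (iii) fast spatial decay of the equal-time
#' correlation of bead displacement vectors (below 10% of its contact
#' value within the half box).
#'
#' @param x A `bd_run` object, or a stress tibble (then supply `log`
#'   and/or `trajectory` if those checks are wanted).
#' @param ... Passed to methods.
#' @return Tibble with one row per check: `check`, `pass`, `statistic`,
#'   `detail`.
#' @export
steady_state_diagnostics <- function(x, ...) {
  UseMethod("steady_state_diagnostics")
}

#' @rdname steady_state_diagnostics
#' @param box_edge Box edge (needed for the velocity-correlation range).
#' @param log Observable log tibble with `Ree2` (optional).
#' @param trajectory List of at least two unwrapped frame matrices
#'   (optional).
#' @export
steady_state_diagnostics.data.frame <- function(x, box_edge = NULL,
                                                log = NULL,
                                                trajectory = NULL, ...) {
  stress <- x
  rows <- list()
  halves_test <- function(v) {
    n <- length(v)
    a <- v[seq_len(floor(n / 2))]
    b <- v[(floor(n / 2) + 1):n]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    z <- abs(mean(a) - mean(b)) / max(se, 1e-300)
    z
  }
  if (!is.null(log) && nrow(log) >= 4) {
    z <- halves_test(log$Ree2)
    rows$stationarity_ree2 <- tibble::tibble(
      check = "stationarity_Ree2", pass = z <= 3, statistic = z,
      detail = "half-difference in units of combined s.e.")
  }
  if (nrow(stress) >= 4) {
    pressure <- -(stress$sxx + stress$syy + stress$szz) / 3
    z <- halves_test(pressure)
    rows$stationarity_p <- tibble::tibble(
      check = "stationarity_pressure", pass = z <= 3, statistic = z,
      detail = "half-difference in units of combined s.e.")
    dmeans <- colMeans(stress[, c("sxx", "syy", "szz")])
    dse <- vapply(stress[, c("sxx", "syy", "szz")], function(v) {
      sqrt(stats::var(v) / length(v))
    }, numeric(1))
    pairs <- utils::combn(3, 2)
    zmax <- max(apply(pairs, 2, function(pr) {
      abs(dmeans[pr[1]] - dmeans[pr[2]]) /
        max(sqrt(dse[pr[1]]^2 + dse[pr[2]]^2), 1e-300)
    }))
    rows$isotropy <- tibble::tibble(
      check = "isotropy", pass = zmax <= 3, statistic = zmax,
      detail = "max pairwise diagonal-stress difference / s.e.")
  }
  if (!is.null(trajectory) && length(trajectory) >= 2 &&
      !is.null(box_edge)) {
    f1 <- trajectory[[length(trajectory) - 1]]
    f2 <- trajectory[[length(trajectory)]]
    v <- f2 - f1
    pos <- f1
    dmat <- as.matrix(stats::dist(pos))
    vv <- v %*% t(v)
    half <- box_edge / 2
    breaks <- seq(0, half, by = 0.5)
    bins <- cut(dmat[upper.tri(dmat)], breaks, labels = FALSE)
    cors <- vv[upper.tri(vv)]
    cv <- vapply(seq_len(length(breaks) - 1), function(b) {
      sel <- which(bins == b)
      if (length(sel) < 5) NA_real_ else mean(cors[sel])
    }, numeric(1))
    c0 <- mean(rowSums(v * v))   # self term: displacement variance
    decayed <- any(!is.na(cv) & abs(cv) <= 0.1 * c0)
    stat <- if (all(is.na(cv))) {
      NA_real_
    } else {
      min(abs(cv) / c0, na.rm = TRUE)
    }
    rows$velcorr <- tibble::tibble(
      check = "velocity_correlation_decay", pass = isTRUE(decayed),
      statistic = stat,
      detail = "min |C_v(r)|/C_v(0) within half box")
  }
  dplyr::bind_rows(rows)
}

#' @rdname steady_state_diagnostics
#' @export
steady_state_diagnostics.bd_run <- function(x, ...) {
  steady_state_diagnostics(x$stress, box_edge = box_edge_of(x$config),
                           log = x$log, trajectory = x$trajectory, ...)
}
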