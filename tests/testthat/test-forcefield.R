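p_std <- sim_params(N = 2, Np = 5, Pe = 0)

test_that("WCA pair force matches its closed form", {
  rc <- 2^(1 / 6)
  expect_equal(wca_pair_force(c(rc, 0, 0)), c(0, 0, 0))
  expect_equal(sqrt(sum(wca_pair_force(c(1, 0, 0))^2)), 24,
               tolerance = 1e-12)
  expect_equal(wca_pair_force(c(2, 0, 0)), c(0, 0, 0))
  # force is along the separation vector and repulsive
  f <- wca_pair_force(c(0.7, 0.7, 0) / sqrt(2))
  expect_gt(sum(f * c(1, 1, 0)), 0)
  expect_error(wca_pair_force(c(0, 0, 0)), "singular")
})

test_that("FENE bond force matches its closed form and domain", {
  f <- fene_bond_force(c(0.75, 0, 0), eps_fene = 30, R0 = 1.5)
  expect_equal(sqrt(sum(f^2)), 30, tolerance = 1e-12)
  expect_lt(f[1], 0)  # attractive: directed to shorten the bond
  # linear small-extension limit: F -> -k r
  tiny <- fene_bond_force(c(1e-6, 0, 0))
  expect_equal(tiny[1], -30e-6, tolerance = 1e-9)
  expect_error(fene_bond_force(c(1.5, 0, 0)), "overstretch")
})

test_that("bending term vanishes for collinear triplets and is local", {
  s <- make_fixture("straight_chain", Np = 6)
  bf <- bending_forces(s, p_std)
  expect_equal(attr(bf, "energy"), 0, tolerance = 1e-12)
  expect_lt(max(abs(c(bf$fx, bf$fy, bf$fz))), 1e-12)

  # right-angle joint with kappa = 1 carries energy 1 kBT
  ra <- polymer_config(tibble::tibble(
    chain = 1L, rank = 0:2,
    x = c(0, 1, 1), y = c(0, 0, 1), z = c(0, 0, 0)), box_edge = 100)
  bf <- bending_forces(ra, p_std, kappa = 1)
  expect_equal(attr(bf, "energy"), 1, tolerance = 1e-12)
  # per-triplet forces sum to zero (translation invariance)
  expect_lt(max(abs(colSums(cbind(bf$fx, bf$fy, bf$fz)))), 1e-12)
})

test_that("bending forces are the exact negative gradient of the energy", {
  set.seed(7)
  pts <- cbind(cumsum(c(0, runif(4, 0.8, 1.1))),
               cumsum(c(0, runif(4, -0.5, 0.5))),
               cumsum(c(0, runif(4, -0.5, 0.5)))) + 50
  cfg <- polymer_config(tibble::tibble(chain = 1L, rank = 0:4,
                                       x = pts[, 1], y = pts[, 2],
                                       z = pts[, 3]), box_edge = 100)
  p <- p_std
  p$kappa <- 1.7
  f <- compute_forces(cfg, p, wca_on = FALSE)
  h <- 1e-6
  for (i in c(1, 3, 5)) {
    for (d in c("x", "y", "z")) {
      up <- cfg; up[[d]][i] <- up[[d]][i] + h
      up[[paste0(d, "u")]][i] <- up[[paste0(d, "u")]][i] + h
      dn <- cfg; dn[[d]][i] <- dn[[d]][i] - h
      dn[[paste0(d, "u")]][i] <- dn[[paste0(d, "u")]][i] - h
      num <- -(potential_energy(up, p, wca_on = FALSE)[["total"]] -
                 potential_energy(dn, p, wca_on = FALSE)[["total"]]) / (2 * h)
      ana <- f[[paste0("f", d, "_total")]][i]
      expect_equal(ana, num, tolerance = 1e-5)
    }
  }
})

test_that("all forces are exact negative gradients on a dense melt", {
  tm <- tiny_melt()
  p <- tm$params
  cfg <- tm$config
  f <- compute_forces(cfg, p)
  h <- 1e-6
  scale <- max(abs(cbind(f$fx_total, f$fy_total, f$fz_total)))
  for (i in c(1, 9, 20)) {
    for (d in c("x", "y", "z")) {
      up <- cfg; up[[d]][i] <- up[[d]][i] + h
      up[[paste0(d, "u")]][i] <- up[[paste0(d, "u")]][i] + h
      dn <- cfg; dn[[d]][i] <- dn[[d]][i] - h
      dn[[paste0(d, "u")]][i] <- dn[[paste0(d, "u")]][i] - h
      num <- -(potential_energy(up, p)[["total"]] -
                 potential_energy(dn, p)[["total"]]) / (2 * h)
      ana <- f[[paste0("f", d, "_total")]][i]
      expect_lt(abs(ana - num) / scale, 1e-6)
    }
  }
})

test_that("conservative force sums vanish (Newton's third law)", {
  tm <- tiny_melt()
  f <- compute_forces(tm$config, tm$params)
  for (comp in c("wca", "fene", "ang")) {
    m <- cbind(f[[paste0("fx_", comp)]], f[[paste0("fy_", comp)]],
               f[[paste0("fz_", comp)]])
    expect_lt(max(abs(colSums(m))), 1e-9)
  }
})

test_that("active forces have constant magnitude and hairpin degeneracy", {
  p <- sim_params(N = 1, Np = 10, Pe = 8)
  s <- make_fixture("straight_chain", Np = 10)
  af <- active_forces(s, p)
  expect_true(all(abs(af$fx - 8) < 1e-12))
  expect_true(all(abs(af$fy) < 1e-12))

  # every bead's active force has magnitude Fp on a curved chain too
  set.seed(1)
  pts <- cbind(cumsum(runif(8, 0.8, 1)), cumsum(runif(8, -0.4, 0.4)),
               cumsum(runif(8, -0.4, 0.4))) + 20
  cc <- polymer_config(tibble::tibble(chain = 1L, rank = 0:7,
                                      x = pts[, 1], y = pts[, 2],
                                      z = pts[, 3]), box_edge = 50)
  af <- active_forces(cc, p)
  expect_equal(sqrt(af$fx^2 + af$fy^2 + af$fz^2), rep(8, 8),
               tolerance = 1e-12)

  # perfect hairpin: antiparallel tangents give zero force at the fold
  h <- make_fixture("hairpin_chain", Np = 7)
  af <- active_forces(h, p)
  mag <- sqrt(af$fx^2 + af$fy^2 + af$fz^2)
  expect_equal(mag[4], 0)          # the fold bead
  expect_equal(mag[1], 8, tolerance = 1e-12)  # tail end, head-ward

  # end beads point head-ward (towards increasing rank)
  s <- make_fixture("straight_chain", Np = 4)
  af <- active_forces(s, p)
  expect_gt(af$fx[1], 0)
  expect_gt(af$fx[4], 0)
})

test_that("virial stress reproduces the hand-evaluated two-bead oracle", {
  # one WCA pair at distance sigma along (1,1,0)/sqrt(2), V = 1000:
  # |F| = 24, ordered double sum gives sxy = -24/(2*1000)*2*12 = -0.012
  beads <- tibble::tibble(chain = 1:2, rank = 0L,
                          x = c(0, 1 / sqrt(2)), y = c(0, 1 / sqrt(2)),
                          z = c(0, 0))
  cfg <- polymer_config(beads, box_edge = 10)
  st <- compute_stress(cfg, p_std)
  expect_equal(st$sxy, -0.012, tolerance = 1e-14)
  expect_equal(st$sxx, -0.012, tolerance = 1e-14)
  expect_equal(st$sxz, 0)
  expect_equal(st$syz, 0)

  # pair separated along x only: all off-diagonals vanish
  cfg2 <- polymer_config(tibble::tibble(chain = 1:2, rank = 0L,
                                        x = c(0, 1), y = 0, z = 0),
                         box_edge = 10)
  st2 <- compute_stress(cfg2, p_std)
  expect_equal(c(st2$sxy, st2$sxz, st2$syz), c(0, 0, 0))

  # no interacting pairs: all components zero
  cfg3 <- make_fixture("isolated_pair", r = 5, box_edge = 10)
  st3 <- compute_stress(cfg3, p_std)
  expect_equal(unlist(st3[, c("sxx", "syy", "szz", "sxy", "sxz", "syz")]),
               setNames(rep(0, 6), c("sxx", "syy", "szz", "sxy", "sxz",
                                     "syz")))
})

test_that("the virial tensor is symmetric for every contribution", {
  p <- sim_params(N = 4, Np = 8, Pe = 6, seed = 21)
  cfg <- soft_pushoff(build_random_melt(p, seed = 21), p, seed = 21)
  f <- compute_forces(cfg, p)
  W <- attr(f, "virials")
  for (w in W) expect_lt(max(abs(w - t(w))), 1e-9)
})

test_that("a thermalised FENE+WCA bond samples the Boltzmann distribution", {
  # dt = 2e-5 keeps the first-order integrator's stationary bias well
  # below the KS tolerance (the bias is ~ dt * k_bond / zeta)
  p <- sim_params(N = 1, Np = 2, Pe = 0, rho_star = 0.01, seed = 9,
                  dt = 2e-5)
  cfg <- build_random_melt(p, seed = 9)
  sched <- run_schedule(2e6, stride_stress = 0, stride_log = 0,
                        stride_bond = 20, steady_state_time = 0)
  run <- bd_run(cfg, p, sched, seed = 9)
  r <- run$bond_samples
  r <- r[-seq_len(500)]  # discard the short equilibration transient
  ecdf_vals <- stats::ecdf(r)(sort(r))
  cdf_vals <- bond_boltzmann_cdf(sort(r))
  D <- max(abs(ecdf_vals - cdf_vals))
  expect_lt(D, 0.01)
})

test_that("sensitivity variants: raw tangent sum and literal bending count", {
  # raw active force on a straight chain: interior beads get 2*Fp
  p <- sim_params(N = 1, Np = 6, Fp = 4, active_raw = TRUE)
  s <- make_fixture("straight_chain", Np = 6)
  af <- active_forces(s, p)
  expect_equal(af$fx[2:5], rep(8, 4), tolerance = 1e-12)
  expect_equal(af$fx[1], 4, tolerance = 1e-12)  # end: single unit tangent

  # literal per-bead triple sum = 3x the unique-pair bending energy
  ra <- polymer_config(tibble::tibble(
    chain = 1L, rank = 0:2,
    x = c(0, 1, 1), y = c(0, 0, 1), z = c(0, 0, 0)), box_edge = 100)
  p1 <- sim_params(N = 1, Np = 3, Pe = 0)
  p3 <- sim_params(N = 1, Np = 3, Pe = 0, bending_overcount = 3)
  e1 <- potential_energy(ra, p1, wca_on = FALSE)[["ang"]]
  e3 <- potential_energy(ra, p3, wca_on = FALSE)[["ang"]]
  expect_equal(e3, 3 * e1, tolerance = 1e-12)
  expect_error(sim_params(N = 1, Np = 3, bending_overcount = 2))
})
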