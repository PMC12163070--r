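test_that("with zero temperature and no forces, positions freeze", {
  p <- sim_params(N = 2, Np = 5, Pe = 0)
  p$kBT <- 0  # deterministic limit
  cfg <- make_fixture("isolated_pair", r = 5, box_edge = 20)
  out <- bd_step(cfg, p, n = 100, seed = 1)
  expect_identical(pos_unwrapped(out), pos_unwrapped(cfg))
})

test_that("a free bead diffuses with MSD = 6 D0 t", {
  # 500 independent single-bead chains, no interactions
  n <- 500
  beads <- tibble::tibble(chain = seq_len(n), rank = 0L,
                          x = stats::runif(n, 0, 50),
                          y = stats::runif(n, 0, 50),
                          z = stats::runif(n, 0, 50))
  cfg <- polymer_config(beads, box_edge = 50)
  p <- sim_params(N = n, Np = 2, Pe = 0, dt = 1e-3)
  sched <- run_schedule(1e4, stride_stress = 0, stride_log = 0,
                        stride_config = 1e4, steady_state_time = 0)
  run <- bd_run(cfg, p, sched, seed = 5, wca_on = FALSE)
  d <- pos_unwrapped(run$config) - pos_unwrapped(cfg)
  msd <- mean(rowSums(d^2))
  t_tot <- 1e4 * 1e-3
  # per-bead |d|^2 has relative sd sqrt(2/3); 3 s.e. over 500 beads
  se3 <- 3 * sqrt(2 / 3) / sqrt(n)
  expect_equal(msd / (6 * p$D0 * t_tot), 1, tolerance = se3)
})

test_that("a straight active chain advects at v = Fp/zeta", {
  p <- sim_params(N = 1, Np = 20, Fp = 8)
  p$kBT <- 0  # remove noise: advection is then exact
  cfg <- make_fixture("straight_chain", Np = 20, box_edge = 100)
  steps <- 5000
  out <- bd_step(cfg, p, n = steps, seed = 1)
  disp <- colMeans(pos_unwrapped(out)) - colMeans(pos_unwrapped(cfg))
  expect_equal(disp[[1]], 8 * steps * p$dt, tolerance = 1e-9)
  expect_equal(disp[[2]], 0, tolerance = 1e-12)
})

test_that("runs are bit-reproducible and restartable for a fixed seed", {
  tm <- tiny_melt()
  sched <- run_schedule(400, stride_stress = 20, stride_log = 0,
                        steady_state_time = 0)
  r1 <- bd_run(tm$config, tm$params, sched, seed = 42)
  r2 <- bd_run(tm$config, tm$params, sched, seed = 42)
  expect_identical(r1$stress, r2$stress)
  expect_identical(pos_unwrapped(r1$config), pos_unwrapped(r2$config))

  r3 <- bd_run(tm$config, tm$params, sched, seed = 43)
  expect_false(identical(r3$stress$sxy, r1$stress$sxy))

  # two half-runs equal one full run: the noise stream is keyed by the
  # global step counter, not by the call
  half <- run_schedule(200, stride_stress = 0, stride_log = 0,
                       steady_state_time = 0)
  a <- bd_run(tm$config, tm$params, half, seed = 42)
  b <- bd_run(a$config, tm$params, half, seed = 42)
  expect_equal(pos_unwrapped(b$config), pos_unwrapped(r1$config),
               tolerance = 1e-12)
})

test_that("stress sampling honours the steady-state onset t > L/v", {
  p <- sim_params(N = 1, Np = 4, Pe = 8)   # L/v = 0.5 tau0
  cfg <- make_fixture("straight_chain", Np = 4, box_edge = 20)
  sched <- run_schedule(6000, stride_stress = 100, stride_log = 0)
  run <- bd_run(cfg, p, sched, seed = 3)
  expect_equal(run$steady_state_time, 0.5)
  expect_gte(min(run$stress$time), 0.5)

  # the interpolation-scale case: L = 100 sigma, Pe = 8 -> 12.5 tau0
  p2 <- sim_params(N = 1, Np = 100, Pe = 8)
  cfg2 <- make_fixture("straight_chain", Np = 100, box_edge = 200)
  run2 <- bd_run(cfg2, p2, run_schedule(1, stride_stress = 1), seed = 1)
  expect_equal(run2$steady_state_time, 12.5)
})

test_that("a phantom freely jointed chain reproduces ideal statistics", {
  # WCA off, kappa = 0: bond vectors are independent, so
  # <Ree^2> = (Np-1) <b^2> exactly in the stationary state
  Np <- 50
  M <- 120
  p <- sim_params(N = M, Np = Np, Pe = 0, kappa = 0, dt = 1e-3,
                  rho_star = 0.05)
  cfg <- build_random_melt(p, seed = 31)
  sched <- run_schedule(5e4, stride_stress = 0, stride_log = 500,
                        stride_config = 10000, steady_state_time = 0)
  run <- bd_run(cfg, p, sched, seed = 31, wca_on = FALSE)
  lg <- run$log
  ree2 <- mean(lg$Ree2[lg$time > 15])
  # mean squared bond length from the stored late frames
  frames <- trajectory_configs(run)
  frames <- frames[attr(run$trajectory, "times") > 15]
  b2 <- mean(vapply(frames, function(f) {
    mean(rowSums(actipoly:::diff_bonds(f)^2))
  }, numeric(1)))
  expect_equal(ree2 / ((Np - 1) * b2), 1, tolerance = 0.05)
})

test_that("halving the timestep leaves the stationary bond length stable", {
  res <- vapply(c(1e-4, 2e-4), function(dt) {
    p <- sim_params(N = 1, Np = 2, Pe = 0, rho_star = 0.01, dt = dt)
    cfg <- build_random_melt(p, seed = 7)
    sched <- run_schedule(round(60 / dt / 10) * 10, stride_stress = 0,
                          stride_log = 0, stride_bond = 10,
                          steady_state_time = 0)
    run <- bd_run(cfg, p, sched, seed = 7)
    mean(run$bond_samples[-seq_len(2000)])
  }, numeric(1))
  expect_lt(abs(res[2] - res[1]) / res[1], 0.005)
})

test_that("instability and overstretch raise errors naming the step", {
  p <- sim_params(N = 1, Np = 2, Pe = 0, dt = 1)  # absurd timestep
  cfg <- polymer_config(tibble::tibble(chain = 1L, rank = 0:1,
                                       x = c(0, 1.4), y = 0, z = 0),
                        box_edge = 20)
  expect_error(bd_step(cfg, p, n = 100, seed = 1),
               "overstretch|instability|step")
})
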