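# closed-form FENE energy, used by the detailed-balance oracle
u_fene <- function(r, k = 30, R0 = 1.5) -0.5 * k * R0^2 * log(1 - (r / R0)^2)

# two parallel straight chains, same x grid, offset d in y
parallel_pair <- function(Np = 6, d = 0.1, b = 0.97, box = 50) {
  xs <- (seq_len(Np) - 1) * b + 10
  polymer_config(tibble::tibble(
    chain = rep(1:2, each = Np), rank = rep(seq_len(Np) - 1L, 2),
    x = rep(xs, 2), y = rep(c(10, 10 + d), each = Np), z = 10),
    box_edge = box)
}

test_that("soft-core push-off is capped and meets its distance criterion", {
  # two beads at r = 0.1 sigma: the soft force stays finite
  p <- sim_params(N = 2, Np = 5, Pe = 0)
  cfg <- make_fixture("isolated_pair", r = 0.1, box_edge = 20)
  out <- bd_run(cfg, p, run_schedule(10, stride_stress = 0, stride_log = 0,
                                     steady_state_time = 0),
                seed = 1, soft_on = TRUE, softA = 10)
  expect_true(all(is.finite(pos_wrapped(out$config))))
  # displacement per step bounded by dt * max soft force = dt * A pi / rc
  d1 <- max(abs(pos_unwrapped(out$config) - pos_unwrapped(cfg)))
  expect_lt(d1, 10 * (p$dt * 10 * pi / 2^(1 / 6) + 4 * sqrt(2 * p$dt)))

  # a full push-off achieves the minimum-distance criterion
  tm <- tiny_melt()
  f <- compute_forces(tm$config, tm$params)
  expect_gte(attr(f, "pair_min"), 0.9)

  # zero amplitude and zero temperature: nothing moves two free beads
  p0 <- sim_params(N = 2, Np = 5, Pe = 0)
  p0$kBT <- 0
  pair <- make_fixture("isolated_pair", r = 0.5, box_edge = 20)
  out0 <- bd_run(pair, p0, run_schedule(50, stride_stress = 0,
                                        stride_log = 0,
                                        steady_state_time = 0),
                 seed = 1, soft_on = TRUE, softA = 0)
  expect_identical(pos_unwrapped(out0$config), pos_unwrapped(pair))
})

test_that("swap moves with dU = 0 are always accepted", {
  # two coincident chains: spliced bonds equal cut bonds exactly
  cfg <- parallel_pair(Np = 6, d = 0)
  p <- sim_params(N = 2, Np = 6, Pe = 0)
  sw <- bond_swap_sweep(cfg, p, n_attempts = 200, seed = 2)
  expect_equal(sw$accepted, 200)
})

test_that("swaps preserve monodispersity, bead count and density", {
  tm <- tiny_melt()
  p <- tm$params
  sw <- bond_swap_sweep(tm$config, p, n_attempts = 500, seed = 3)
  rep <- validate_topology(sw$config, p)
  expect_true(rep$ok)
  expect_equal(nrow(sw$config), nrow(tm$config))
  expect_equal(nrow(rep$chain_length_histogram), 1)
  expect_equal(rep$chain_length_histogram$len, p$Np)
  # positions themselves never move in a swap: sorted coordinates agree
  expect_equal(sort(sw$config$xu), sort(tm$config$xu))
})

test_that("reconnections that would overstretch a bond are auto-rejected", {
  # offset 1.6 sigma > R0: every proposed splice is invalid
  cfg <- parallel_pair(Np = 6, d = 1.6)
  p <- sim_params(N = 2, Np = 6, Pe = 0)
  sw <- bond_swap_sweep(cfg, p, n_attempts = 300, seed = 4, elig_r = 5)
  expect_equal(sw$accepted, 0)
})

test_that("swap Monte Carlo satisfies detailed balance on a two-chain system", {
  # parallel chains offset d: each bond rank is an independent two-state
  # system, uncrossed (bond b) or crossed (bond sqrt(b^2+d^2)), with
  # energy cost c = 2 * [U_fene(crossed) - U_fene(b)]; kappa = 0 makes
  # ranks exactly independent, so P(crossed) = exp(-c)/(1+exp(-c))
  b <- 0.97
  d <- 0.1
  Np <- 6
  r_cross <- sqrt(b^2 + d^2)
  cost <- 2 * (u_fene(r_cross) - u_fene(b))
  p_cross <- exp(-cost) / (1 + exp(-cost))

  p <- sim_params(N = 2, Np = Np, Pe = 0, kappa = 0)
  cfg0 <- parallel_pair(Np = Np, d = d)
  thresh <- (b + r_cross) / 2
  crossed_fraction <- function(cfg) {
    bl <- sqrt(rowSums(actipoly:::diff_bonds(cfg)^2))
    mean(bl > thresh)
  }
  hits <- vapply(seq_len(3000), function(rep) {
    sw <- bond_swap_sweep(cfg0, p, n_attempts = 400, seed = 10000 + rep)
    crossed_fraction(sw$config)
  }, numeric(1))
  expect_lt(abs(mean(hits) - p_cross), 0.01)
})

test_that("equilibration is stationary on an already-equilibrated melt", {
  tm <- tiny_melt()
  p <- tm$params
  eq1 <- suppressWarnings(
    equilibrate(tm$config, p, bd_steps = 1000, max_blocks = 20, seed = 6))
  eq2 <- equilibrate(eq1$config, p, bd_steps = 1000, min_blocks = 4,
                     max_blocks = 20, seed = 7)
  expect_true(eq2$converged)
  expect_equal(nrow(eq2$config), nrow(tm$config))
})

test_that("equilibrated flexible melts show the ideal-chain internal-distance plateau", {
  # Np = 12 keeps the Rouse time (~5 tau0) well inside the run budget
  p <- sim_params(N = 20, Np = 12, Pe = 0, seed = 17)
  eq <- suppressWarnings(prepare_melt(p, bd_steps = 5000, sweeps = 1,
                                      min_blocks = 6, max_blocks = 30))
  msid <- internal_distances(eq$config, n_values = c(1, 2, 4, 8, 11))
  b2 <- msid$r2[msid$n == 1]
  # freely-rotating estimate: C_inf = (1+<cos>)/(1-<cos>) with
  # <cos theta> = coth(kappa) - 1/kappa for the kappa(1 - cos) potential
  ck <- 1 / tanh(p$kappa) - 1 / p$kappa
  c_inf <- (1 + ck) / (1 - ck)
  plateau <- msid$r2_per_n[msid$n >= 8] / b2
  # approaches a constant of order C_inf (finite-n and melt corrections
  # permitted; chain-count noise ~15%)
  expect_true(all(plateau > 0.55 * c_inf & plateau < 1.5 * c_inf))
  expect_lt(abs(diff(log(plateau))), 0.4)
})
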