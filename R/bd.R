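#' Sampling schedule for a Brownian-dynamics run
#'
#' @param n_steps Number of integration steps.
#' @param stride_stress Steps between virial-stress samples (0 disables).
#' @param stride_config Steps between stored trajectory frames (0 disables).
#' @param stride_log Steps between observable-log rows (energies, mean
#'   squared end-to-end distance, bond extremes).
#' @param steady_state_time Time (tau0) before which no stress is sampled.
#'   `NULL` selects the default: `L/v` for an active run (the time for a
#'   chain to crawl its own contour length, after which the melt is in its
#'   propulsive steady state), 0 for a passive run.
#' @param stride_bond Steps between samples of the first bond length
#'   (0 disables; used for bond-distribution diagnostics).
#' @return A `run_schedule` list.
#' @export
run_schedule <- function(n_steps, stride_stress = 10, stride_config = 0,
                         stride_log = 1000, steady_state_time = NULL,
                         stride_bond = 0) {
  stopifnot(n_steps >= 1, stride_stress >= 0, stride_config >= 0,
            stride_log >= 0, stride_bond >= 0,
            is.null(steady_state_time) || steady_state_time >= 0)
  structure(list(n_steps = as.integer(n_steps),
                 stride_stress = as.integer(stride_stress),
                 stride_config = as.integer(stride_config),
                 stride_log = as.integer(stride_log),
                 stride_bond = as.integer(stride_bond),
                 steady_state_time = steady_state_time),
            class = "run_schedule")
}

#' Integrate the overdamped Langevin dynamics
#'
#' Euler-Maruyama update
#' `r_i <- r_i + (dt/zeta) (-grad_i U + F_p,i) + xi_i`, with `xi_i`
#' Gaussian, zero mean and variance `2 D0 dt` per component, independent
#' across beads, components and steps. Wrapped positions are re-imaged
#' every step; unwrapped positions accumulate the same displacements. The
#' noise stream is keyed by `(seed, step, bead)`, so runs are bit
#' reproducible and restartable.
#'
#' @param config Starting [polymer_config()].
#' @param params A [sim_params()] object.
#' @param schedule A [run_schedule()].
#' @param seed Integer RNG seed.
#' @param wca_on Evaluate WCA repulsion (`FALSE` for phantom chains).
#' @param include_active_stress Include the tangential active terms in the
#'   sampled virial stress.
#' @param soft_on,softA Replace WCA by the capped soft-core repulsion of
#'   amplitude `softA` (used internally by [soft_pushoff()]).
#' @return A list of class `bd_run` with elements `config` (final state),
#'   `stress` (tibble: `time, sxx..syz, volume`), `log` (tibble of
#'   energies and chain observables), `trajectory` (list of unwrapped
#'   frame matrices with attribute `times`, or `NULL`), `params`,
#'   `schedule`, `seed`.
#' @export
bd_run <- function(config, params, schedule, seed = params$seed,
                   wca_on = TRUE, include_active_stress = TRUE,
                   soft_on = FALSE, softA = 0) {
  stopifnot(inherits(schedule, "run_schedule"))
  steady <- schedule$steady_state_time
  if (is.null(steady)) {
    steady <- if (params$v > 0) params$L / params$v else 0
  }
  par <- ff_par(params, box_edge_of(config), wca_on = wca_on && !soft_on,
                soft_on = soft_on, softA = softA,
                active_virial = include_active_stress)
  res <- cpp_bd_run(pos_wrapped(config), pos_unwrapped(config), config$chain,
                    par, params$kBT, params$zeta, params$dt,
                    schedule$n_steps, seed, step_of(config), time_of(config),
                    schedule$stride_stress, steady, schedule$stride_config,
                    schedule$stride_log, schedule$stride_bond)
  stress <- tibble::as_tibble(as.data.frame(res$stress))
  names(stress) <- c("time", "sxx", "syy", "szz", "sxy", "sxz", "syz",
                     "volume")
  lg <- tibble::as_tibble(as.data.frame(res$log))
  names(lg) <- c("time", "E_pair", "E_fene", "E_ang", "Ree2", "bond_min",
                 "bond_max")
  traj <- NULL
  if (length(res$traj) > 0) {
    traj <- res$traj
    attr(traj, "times") <- res$traj_times
  }
  final <- update_config(config, posW = res$posW, posU = res$posU,
                         time = res$time_end, step = res$step_end)
  structure(list(config = final, stress = stress, log = lg,
                 trajectory = traj,
                 bond_samples = res$bond_samples,
                 params = params, schedule = schedule, seed = seed,
                 steady_state_time = steady),
            class = "bd_run")
}

#' @export
print.bd_run <- function(x, ...) {
  cat("<bd_run> ", x$schedule$n_steps, " steps, dt = ", x$params$dt,
      " tau0; ", nrow(x$stress), " stress samples (t >= ",
      signif(x$steady_state_time, 4), "), ",
      if (is.null(x$trajectory)) 0 else length(x$trajectory),
      " frames\n", sep = "")
  invisible(x)
}

#' Advance a configuration by a few integration steps
#'
#' Convenience wrapper around [bd_run()] without any sampling.
#'
#' @inheritParams bd_run
#' @param n Number of steps.
#' @return The advanced [polymer_config()].
#' @export
bd_step <- function(config, params, n = 1, seed = params$seed,
                    wca_on = TRUE) {
  sched <- run_schedule(n, stride_stress = 0, stride_config = 0,
                        stride_log = 0, steady_state_time = 0)
  bd_run(config, params, sched, seed = seed, wca_on = wca_on)$config
}

#' Stored trajectory frames as configuration objects
#'
#' @param run A `bd_run` with stored frames.
#' @return List of [polymer_config()] frames (empty if none stored).
#' @export
trajectory_configs <- function(run) {
  if (is.null(run$trajectory)) return(list())
  times <- attr(run$trajectory, "times")
  box <- box_edge_of(run$config)
  lapply(seq_along(run$trajectory), function(i) {
    pu <- run$trajectory[[i]]
    pw <- pu - box * floor(pu / box)
    update_config(run$config, posW = pw, posU = pu, time = times[i])
  })
}

#' Mean-square displacement of beads from a stored trajectory
#'
#' @param run A `bd_run` with stored frames.
#' @return Tibble with lag time `t` and `msd` averaged over beads and time
#'   origins (every frame pair at that lag).
#' @export
bead_msd <- function(run) {
  stopifnot(!is.null(run$trajectory))
  frames <- run$trajectory
  times <- attr(frames, "times")
  nf <- length(frames)
  lags <- seq_len(nf - 1)
  msd <- vapply(lags, function(l) {
    s <- 0
    cnt <- 0
    for (i in seq_len(nf - l)) {
      d <- frames[[i + l]] - frames[[i]]
      s <- s + mean(rowSums(d^2))
      cnt <- cnt + 1
    }
    s / cnt
  }, numeric(1))
  tibble::tibble(t = times[1 + lags] - times[1], msd = msd)
}
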