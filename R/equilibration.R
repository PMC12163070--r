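#' Soft push-off of an overlapping random-walk melt
#'
#' Replaces the WCA repulsion by the capped soft-core potential
#' `U_soft(r) = A (1 + cos(pi r / r_c))` below `r_c = 2^(1/6) sigma`
#' (finite at full overlap) and runs short Brownian-dynamics blocks while
#' ramping the amplitude `A`, then switches the full WCA interaction back
#' on. Succeeds when the minimum non-bonded pair distance reaches
#' `min_dist`; otherwise aborts with diagnostics.
#'
#' @param config A fresh [build_random_melt()] configuration (overlaps
#'   allowed).
#' @param params A [sim_params()] object (activity is ignored here; the
#'   push-off runs passively).
#' @param amplitudes Ramp of soft-core amplitudes A (kBT).
#' @param steps_per_stage BD steps at each amplitude.
#' @param min_dist Exit criterion on the minimum pair distance (sigma).
#' @param seed RNG seed.
#' @return The pushed-off [polymer_config()].
#' @export
soft_pushoff <- function(config, params,
                         amplitudes = c(1, 2, 5, 10, 20, 50, 100),
                         steps_per_stage = 1000, min_dist = 0.9,
                         seed = params$seed) {
  p <- params
  p$Fp <- 0   # push-off is passive
  sched <- run_schedule(steps_per_stage, stride_stress = 0,
                        stride_config = 0, stride_log = 0,
                        steady_state_time = 0)
  for (A in amplitudes) {
    run <- bd_run(config, p, sched, seed = seed, soft_on = TRUE, softA = A)
    config <- run$config
  }
  f <- forces_raw(config, p, wca_on = TRUE)
  if (is.finite(f$pair_min) && f$pair_min < min_dist) {
    stop("soft push-off failed: minimum pair distance ",
         signif(f$pair_min, 4), " sigma < ", min_dist,
         " sigma after the amplitude ramp (", length(amplitudes),
         " stages x ", steps_per_stage, " steps); extend the ramp")
  }
  config
}

#' One sweep of double-bridging bond-swap Monte Carlo
#'
#' Topology-changing equilibration move for a monodisperse melt: a bond at
#' rank `a` on chain A and the bond at the same rank on another chain B
#' are cut and the tails beyond rank `a` exchanged, preserving both chain
#' lengths and all bead positions exactly. A proposal is rejected outright
#' unless all four involved bonds (the two cut and the two spliced) are
#' shorter than the eligibility radius, which keeps the proposal symmetric
#' (a spliced bond at or beyond `R0` is likewise auto-rejected); otherwise
#' it is accepted with the Metropolis probability
#' `min(1, exp(-dU/kBT))`, where `dU` collects the FENE and bending
#' changes of the affected bonds and joints (positions do not move, so WCA
#' terms cancel).
#'
#' @param config A monodisperse [polymer_config()].
#' @param params A [sim_params()] object.
#' @param n_attempts Attempted moves; defaults to one per bead.
#' @param elig_r Eligibility radius (sigma) for all four involved bonds.
#' @param seed RNG seed.
#' @param mc_counter Starting value of the proposal counter (lets repeated
#'   sweeps continue one reproducible stream).
#' @return List with the updated `config`, `accepted`, `attempted`,
#'   the per-attempt `accept_flags`, and `mc_counter` to pass to the next
#'   sweep.
#' @export
bond_swap_sweep <- function(config, params, n_attempts = NULL, elig_r = 1.3,
                            seed = params$seed, mc_counter = 0) {
  n_chain <- dplyr::n_distinct(config$chain)
  np <- nrow(config) / n_chain
  if (np != round(np)) stop("bond swaps require a monodisperse melt")
  if (n_chain < 2) stop("bond swaps need at least two chains")
  n_attempts <- n_attempts %||% nrow(config)
  res <- cpp_swap_sweep(pos_wrapped(config), pos_unwrapped(config),
                        n_chain, as.integer(np), box_edge_of(config),
                        params$eps_fene, params$R0, params$kappa,
                        params$kBT, elig_r, as.integer(n_attempts),
                        seed, mc_counter)
  list(config = update_config(config, posW = res$posW, posU = res$posU),
       accepted = res$accepted, attempted = res$attempted,
       accept_flags = res$accept_flags, mc_counter = res$ctr_end)
}

#' Internal-distance curve of a melt
#'
#' Mean squared internal distance `<R^2(n)>` between beads `n` apart along
#' the same chain, averaged over chains and starting beads; `<R^2(n)>/n`
#' approaching a constant at large `n` is the ideal-chain signature used
#' as the equilibration criterion.
#'
#' @param config A [polymer_config()].
#' @param n_values Separations to evaluate (defaults to a log-ish grid up
#'   to `Np - 1`).
#' @return Tibble with `n`, `r2` and `r2_per_n`.
#' @export
internal_distances <- function(config, n_values = NULL) {
  pu <- pos_unwrapped(config)
  chains <- split(seq_len(nrow(config)), config$chain)
  np <- max(lengths(chains))
  n_values <- n_values %||% unique(round(exp(seq(0, log(np - 1),
                                                 length.out = 12))))
  r2 <- vapply(n_values, function(n) {
    acc <- 0
    cnt <- 0
    for (idx in chains) {
      if (length(idx) <= n) next
      a <- pu[idx[seq_len(length(idx) - n)], , drop = FALSE]
      b <- pu[idx[seq_len(length(idx) - n) + n], , drop = FALSE]
      acc <- acc + sum((b - a)^2)
      cnt <- cnt + nrow(a)
    }
    if (cnt == 0) NA_real_ else acc / cnt
  }, numeric(1))
  tibble::tibble(n = n_values, r2 = r2, r2_per_n = r2 / n_values)
}

#' Equilibrate a melt by alternating dynamics and bond swaps
#'
#' Alternates passive Brownian-dynamics blocks with double-bridging sweeps
#' until the mean squared end-to-end distance and the internal-distance
#' curve `<R^2(n)>/n` are stationary: the relative change between the two
#' halves of the accumulated history falls below `tol`. Bead count and
#' density are never altered.
#'
#' @param config Pushed-off [polymer_config()].
#' @param params A [sim_params()] object (equilibration runs passively).
#' @param bd_steps BD steps per block.
#' @param sweeps Bond-swap sweeps per block.
#' @param min_blocks,max_blocks Bounds on the number of blocks.
#' @param tol Relative stationarity tolerance.
#' @param seed RNG seed.
#' @return A list of class `equilibration` with `config`, `converged`,
#'   `history` (per-block `Ree2`, swap acceptance), and `msid` (the final
#'   internal-distance curve).
#' @export
equilibrate <- function(config, params, bd_steps = 2000, sweeps = 2,
                        min_blocks = 4, max_blocks = 40, tol = 0.02,
                        seed = params$seed) {
  p <- params
  p$Fp <- 0
  sched <- run_schedule(bd_steps, stride_stress = 0, stride_config = 0,
                        stride_log = 0, steady_state_time = 0)
  hist <- list()
  msid_prev <- NULL
  mc <- 0
  converged <- FALSE
  for (blk in seq_len(max_blocks)) {
    run <- bd_run(config, p, sched, seed = seed)
    config <- run$config
    acc <- 0
    att <- 0
    for (s in seq_len(sweeps)) {
      sw <- bond_swap_sweep(config, p, seed = seed, mc_counter = mc)
      config <- sw$config
      mc <- sw$mc_counter
      acc <- acc + sw$accepted
      att <- att + sw$attempted
    }
    ree2 <- mean_ree2(config)
    hist[[blk]] <- tibble::tibble(block = blk, time = time_of(config),
                                  Ree2 = ree2,
                                  swap_acceptance = acc / max(1, att))
    if (blk >= min_blocks) {
      r <- vapply(hist, function(h) h$Ree2, numeric(1))
      a <- r[seq_len(floor(blk / 2))]
      b <- r[(floor(blk / 2) + 1):blk]
      # stationary when the half-means agree within tol or within noise
      se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
      ree_ok <- abs(mean(b) - mean(a)) <
        max(tol * abs(mean(a)), 2 * se)
      msid <- internal_distances(config)
      msid_ok <- !is.null(msid_prev) &&
        stats::median(abs(msid$r2_per_n - msid_prev$r2_per_n) /
                        pmax(msid_prev$r2_per_n, 1e-12),
                      na.rm = TRUE) < 2 * tol
      msid_prev <- msid
      if (ree_ok && msid_ok) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("equilibrate(): stationarity not reached within ", max_blocks,
            " blocks; returning the last configuration with its report")
  }
  structure(list(config = config, converged = converged,
                 history = dplyr::bind_rows(hist),
                 msid = internal_distances(config)),
            class = "equilibration")
}

# mean squared end-to-end distance over chains (unwrapped authority)
mean_ree2 <- function(config) {
  pu <- pos_unwrapped(config)
  idx <- split(seq_len(nrow(config)), config$chain)
  mean(vapply(idx, function(i) {
    d <- pu[i[length(i)], ] - pu[i[1], ]
    sum(d^2)
  }, numeric(1)))
}

#' Build, push off and equilibrate a melt in one call
#'
#' @param params A [sim_params()] object.
#' @param seed RNG seed.
#' @param ... Passed to [equilibrate()].
#' @return An `equilibration` object (see [equilibrate()]).
#' @export
prepare_melt <- function(params, seed = params$seed, ...) {
  cfg <- build_random_melt(params, seed = seed)
  cfg <- soft_pushoff(cfg, params, seed = seed)
  equilibrate(cfg, params, seed = seed, ...)
}
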