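#' Primitive-path contraction
#'
#' Contracts every chain to (an approximation of) the shortest path
#' between its two fixed ends that preserves topological uncrossability
#' with all other chains: each interior node is iteratively pulled toward
#' the chord between its neighbours, a move being accepted only when the
#' swept triangles intersect no segment of any other chain (with
#' backtracking line search when blocked), and nearly collinear nodes are
#' removed. By default all chains contract simultaneously against each
#' other (primitive-path-network practice); `mode = "fixed"` contracts
#' against the frozen input conformations instead (used by the geometric
#' oracle tests). Periodic images of obstacle segments are replicated
#' within a one-bead-diameter shell around each contracting chain.
#'
#' The iteration is deterministic (chains in index order, nodes in rank
#' order) and monotone: the total path length never increases.
#'
#' @param config A [polymer_config()]; unwrapped coordinates are used.
#' @param mode `"simultaneous"` (self-consistent network) or `"fixed"`
#'   (frozen obstacles).
#' @param periodic Replicate obstacles over periodic images.
#' @param kink_thresh Angular deviation (rad) below which a node counts
#'   as collinear and above which a remaining interior node counts as a
#'   kink.
#' @param tol Convergence tolerance: stop when a sweep shortens the total
#'   path length by less than `tol` (sigma).
#' @param max_sweeps Sweep budget; non-convergence yields a warning and
#'   the best result.
#' @param shell Obstacle replication shell (sigma).
#' @return An object of class `ppa_result`: a list with `chains` (tibble:
#'   `chain`, `Lpp`, `Z`, `Ree`, `n_nodes`), `Ne` (ensemble entanglement
#'   length from [entanglement_length()]), `paths` (list of node
#'   matrices), `length_trace`, `sweeps`, `converged`, `Np`.
#' @export
ppa_contract <- function(config, mode = c("simultaneous", "fixed"),
                         periodic = TRUE, kink_thresh = 1e-3, tol = 1e-6,
                         max_sweeps = 2000, shell = 1) {
  mode <- match.arg(mode)
  res <- cpp_ppa_contract(pos_unwrapped(config), config$chain,
                          box_edge_of(config), periodic,
                          mode == "fixed", kink_thresh, tol,
                          as.integer(max_sweeps), shell)
  if (!res$converged) {
    warning("primitive-path contraction did not converge within ",
            max_sweeps, " sweeps; returning the best result")
  }
  chains <- tibble::tibble(chain = res$chain, Lpp = res$Lpp, Z = res$Z,
                           Ree = res$Ree, n_nodes = res$n_nodes)
  np <- unique(table(config$chain))
  Ne <- if (length(np) == 1) {
    entanglement_length(chains, Np = as.integer(np))
  } else {
    NA_real_
  }
  structure(list(chains = chains, Ne = Ne, paths = res$paths,
                 length_trace = res$length_trace, sweeps = res$sweeps,
                 converged = res$converged,
                 Np = if (length(np) == 1) as.integer(np) else NA_integer_,
                 time = time_of(config)),
            class = "ppa_result")
}

#' @export
print.ppa_result <- function(x, ...) {
  cat("<ppa_result> ", nrow(x$chains), " chains; <Lpp> = ",
      signif(mean(x$chains$Lpp), 5), " sigma, <Z> = ",
      signif(mean(x$chains$Z), 4), ", Ne = ", signif(x$Ne, 4),
      " (", x$sweeps, " sweeps",
      if (x$converged) ", converged" else ", NOT converged", ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy ppa_result
#' @export
tidy.ppa_result <- function(x, ...) x$chains

#' @method glance ppa_result
#' @export
glance.ppa_result <- function(x, ...) {
  tibble::tibble(Ne = x$Ne, Lpp_mean = mean(x$chains$Lpp),
                 Z_mean = mean(x$chains$Z),
                 Ree_mean = mean(x$chains$Ree),
                 sweeps = x$sweeps, converged = x$converged)
}

#' Entanglement length from primitive-path statistics
#'
#' `Ne = (Np - 1) <Ree^2> / <Lpp^2>` with ensemble means of squares; for
#' unentangled chains (`Lpp = Ree`) this reduces to `Np - 1`.
#'
#' @param chains Tibble with per-chain `Ree` and `Lpp` (e.g.
#'   `tidy(ppa_result)`), or a `ppa_result`.
#' @param Np Beads per chain.
#' @return Entanglement length in beads.
#' @export
entanglement_length <- function(chains, Np) {
  if (inherits(chains, "ppa_result")) chains <- chains$chains
  if (nrow(chains) < 1) stop("need at least one chain result")
  ml2 <- mean(chains$Lpp^2)
  if (ml2 == 0) stop("<Lpp^2> is zero")
  (Np - 1) * mean(chains$Ree^2) / ml2
}

#' Equilibrium plateau-modulus prediction from the entanglement length
#'
#' The standard tube-model estimate `G0 ~ 4 rho kBT / (5 Ne^0)` for an
#' equilibrium entangled melt of number density `rho* / sigma^3`.
#'
#' @param rho_star Dimensionless number density.
#' @param Ne0 Equilibrium entanglement length (beads).
#' @param kBT Thermal energy.
#' @param sigma Bead diameter.
#' @return Predicted plateau modulus (kBT/sigma^3).
#' @examples
#' equilibrium_plateau_prediction(0.85, 41)  # ~0.0166
#' @export
equilibrium_plateau_prediction <- function(rho_star, Ne0, kBT = 1,
                                           sigma = 1) {
  stopifnot(Ne0 > 0)
  4 * rho_star * kBT / (5 * Ne0 * sigma^3)
}

#' Primitive-path observables along a trajectory
#'
#' Runs the contraction on every frame and reports `Lpp`, `Z`, `Ne` and
#' `Ree`, optionally normalized by a passive (Pe = 0) reference, against
#' the rescaled time `t v / L`.
#'
#' @param frames List of [polymer_config()] frames (e.g. from
#'   `trajectory_configs()` of a `bd_run`), or a `bd_run` with stored
#'   frames.
#' @param reference Optional passive reference: a `ppa_result` or a
#'   one-row list/tibble with `Lpp0`, `Z0`, `Ne0` (absolute curves are
#'   returned when missing).
#' @param v,L Self-propulsion speed and contour length used for the time
#'   rescaling (taken from `params` when `frames` is a `bd_run`).
#' @param ... Passed to [ppa_contract()].
#' @return Tibble of class `ppa_timeseries`: `time`, `tv_over_L`, `Lpp`,
#'   `Z`, `Ne`, `Ree`, and when a reference is given `Lpp_rel`, `Z_rel`,
#'   `Ne_rel`.
#' @export
ppa_timeseries <- function(frames, reference = NULL, v = NULL, L = NULL,
                           ...) {
  if (inherits(frames, "bd_run")) {
    v <- v %||% frames$params$v
    L <- L %||% frames$params$L
    frames <- trajectory_configs(frames)
  }
  stopifnot(length(frames) >= 1)
  rows <- purrr::map_dfr(frames, function(cfg) {
    r <- ppa_contract(cfg, ...)
    tibble::tibble(time = time_of(cfg), Lpp = mean(r$chains$Lpp),
                   Z = mean(r$chains$Z), Ne = r$Ne,
                   Ree = mean(r$chains$Ree))
  })
  if (!is.null(v) && !is.null(L) && v > 0) {
    rows$tv_over_L <- rows$time * v / L
  } else {
    rows$tv_over_L <- NA_real_
  }
  if (!is.null(reference)) {
    if (inherits(reference, "ppa_result")) {
      reference <- list(Lpp0 = mean(reference$chains$Lpp),
                        Z0 = mean(reference$chains$Z),
                        Ne0 = reference$Ne)
    }
    rows$Lpp_rel <- rows$Lpp / reference$Lpp0
    rows$Z_rel <- rows$Z / reference$Z0
    rows$Ne_rel <- rows$Ne / reference$Ne0
  }
  class(rows) <- c("ppa_timeseries", class(rows))
  rows
}
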