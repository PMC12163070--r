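#' WCA pair force on the first bead of a pair
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones force, cut off at
#' `2^(1/6) sigma`. Returns the force on the bead at the head of the
#' separation vector `r_vec = r_1 - r_2`.
#'
#' @param r_vec Separation vector (length-3 numeric).
#' @param eps_wca Energy scale (kBT).
#' @param sigma Bead diameter.
#' @return Force vector (kBT/sigma) on bead 1.
#' @examples
#' sqrt(sum(wca_pair_force(c(1, 0, 0))^2))  # 24 at r = sigma
#' @export
wca_pair_force <- function(r_vec, eps_wca = 1, sigma = 1) {
  r2 <- sum(r_vec^2)
  if (r2 == 0) stop("singular overlap: |r_vec| = 0")
  rc2 <- 2^(1 / 3) * sigma^2
  if (r2 >= rc2) return(c(0, 0, 0))
  sr2 <- sigma^2 / r2
  sr6 <- sr2^3
  (24 * eps_wca * (2 * sr6^2 - sr6) / r2) * r_vec
}

#' FENE bond force on the first bead of a bonded pair
#'
#' Finitely extensible nonlinear elastic spring
#' `F(r) = -k r / (1 - (r/R0)^2)` with spring constant `k = eps_fene`
#' (kBT/sigma^2), diverging at the maximum extension `R0`.
#'
#' @param r_vec Bond vector `r_1 - r_2`.
#' @param eps_fene Spring constant (kBT/sigma^2).
#' @param R0 Maximum bond extension (sigma).
#' @return Force vector on bead 1 (directed to shorten the bond).
#' @export
fene_bond_force <- function(r_vec, eps_fene = 30, R0 = 1.5) {
  r2 <- sum(r_vec^2)
  if (r2 >= R0^2) {
    stop("FENE bond overstretched: |r_vec| >= R0 = ", R0)
  }
  (-eps_fene / (1 - r2 / R0^2)) * r_vec
}

# internal: run the C++ force kernel on a config
forces_raw <- function(config, params, wca_on = TRUE, soft_on = FALSE,
                       softA = 0, Fp = NULL, active_virial = TRUE) {
  par <- ff_par(params, box_edge_of(config), wca_on = wca_on,
                soft_on = soft_on, softA = softA, Fp = Fp,
                active_virial = active_virial)
  cpp_forces(pos_wrapped(config), pos_unwrapped(config), config$chain, par)
}

#' Evaluate all deterministic forces on every bead
#'
#' Computes the WCA, FENE, bending and tangential active contributions and
#' their total for each bead, the potential-energy components, and the
#' per-contribution virial sums.
#'
#' @param config A [polymer_config()].
#' @param params A [sim_params()] object.
#' @param wca_on Evaluate the WCA repulsion (set `FALSE` for phantom
#'   chains).
#' @return A tibble of class `bead_forces` with per-bead force components
#'   `f<α>_wca`, `f<α>_fene`, `f<α>_ang`, `f<α>_active`, `f<α>_total` and
#'   attributes `energies` and `virials`.
#' @export
compute_forces <- function(config, params, wca_on = TRUE) {
  f <- forces_raw(config, params, wca_on = wca_on)
  out <- tibble::tibble(chain = config$chain, rank = config$rank)
  lab <- c("x", "y", "z")
  for (comp in c("wca", "fene", "ang", "active", "total")) {
    m <- f[[paste0("f_", comp)]]
    for (d in 1:3) out[[paste0("f", lab[d], "_", comp)]] <- m[, d]
  }
  structure(out,
            energies = c(pair = f$E_pair, fene = f$E_fene, ang = f$E_ang),
            virials = list(pair = f$W_pair, ang = f$W_ang,
                           active = f$W_active),
            bond_range = c(f$bond_min, f$bond_max),
            pair_min = f$pair_min,
            class = c("bead_forces", class(out)))
}

#' Bending forces from the backbone potential
#'
#' The bending energy is `kappa * sum_j (1 - t_j . t_{j+1})` over unique
#' consecutive-tangent pairs along each chain; forces are the exact
#' analytic negative gradient (evaluated through the central pairwise
#' decomposition, so per-triplet forces sum to zero and the virial is
#' symmetric).
#'
#' @inheritParams compute_forces
#' @param kappa Bending stiffness (kBT); defaults to `params$kappa`.
#' @return Tibble with per-bead `fx, fy, fz` and attribute `energy`.
#' @export
bending_forces <- function(config, params, kappa = NULL) {
  p <- params
  if (!is.null(kappa)) p$kappa <- kappa
  f <- forces_raw(config, p, wca_on = FALSE, Fp = 0)
  structure(
    tibble::tibble(chain = config$chain, rank = config$rank,
                   fx = f$f_ang[, 1], fy = f$f_ang[, 2], fz = f$f_ang[, 3]),
    energy = f$E_ang
  )
}

#' Tangential active forces
#'
#' Each interior bead is propelled along the normalized sum of its two
#' adjacent bond tangents with constant magnitude `Fp`; end beads are
#' propelled head-ward along their single adjacent tangent. A bead whose
#' adjacent tangents are antiparallel (`|t1 + t2| < 1e-8`, a perfect
#' hairpin) receives zero active force.
#'
#' @inheritParams compute_forces
#' @param Fp Active force magnitude; defaults to `params$Fp`.
#' @return Tibble with per-bead `fx, fy, fz`.
#' @export
active_forces <- function(config, params, Fp = NULL) {
  p <- params
  p$kappa <- 0
  f <- forces_raw(config, p, wca_on = FALSE, Fp = Fp %||% params$Fp)
  tibble::tibble(chain = config$chain, rank = config$rank,
                 fx = f$f_active[, 1], fy = f$f_active[, 2],
                 fz = f$f_active[, 3])
}

#' Total potential energy of a configuration
#'
#' @inheritParams compute_forces
#' @return Named numeric vector `c(pair, fene, ang, total)` in kBT.
#' @export
potential_energy <- function(config, params, wca_on = TRUE) {
  f <- forces_raw(config, params, wca_on = wca_on)
  c(pair = f$E_pair, fene = f$E_fene, ang = f$E_ang,
    total = f$E_pair + f$E_fene + f$E_ang)
}

#' Instantaneous virial stress tensor
#'
#' Off-diagonal and diagonal components of the virial stress,
#' `sigma_ab = -1/(2V) sum_k sum_l F_kl^a r_kl^b`, evaluated from the
#' pairwise decomposition of all interactions (WCA and FENE pairs
#' directly; bending through the central three-body decomposition; the
#' tangential active terms attributed to their generating bond pair,
#' included by default and switchable off).
#'
#' @inheritParams compute_forces
#' @param include_active Include the active tangential contribution.
#' @return One-row tibble of class `stress_sample` with columns `time`,
#'   `sxx, syy, szz, sxy, sxz, syz` (kBT/sigma^3) and `volume`.
#' @export
compute_stress <- function(config, params, include_active = TRUE) {
  f <- forces_raw(config, params, active_virial = include_active)
  vol <- box_edge_of(config)^3
  W <- f$W_pair + f$W_ang + if (include_active) f$W_active else 0
  S <- -(W + t(W)) / (2 * vol)
  tibble::tibble(time = time_of(config),
                 sxx = S[1, 1], syy = S[2, 2], szz = S[3, 3],
                 sxy = S[1, 2], sxz = S[1, 3], syz = S[2, 3],
                 volume = vol)
}
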