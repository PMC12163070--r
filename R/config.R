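#' Polymer configuration tibbles
#'
#' A polymer configuration is a tibble with one row per bead, ordered by
#' `(chain, rank)`, carrying wrapped coordinates `x, y, z` (inside the
#' periodic box), unwrapped coordinates `xu, yu, zu` (accumulated image
#' shifts; the authority for end-to-end distances, primitive paths and
#' mean-square displacements), the integer `chain` id and the 0-based
#' `rank` of the bead along its chain. The cubic box edge and the
#' simulation time are stored as attributes `box_edge` and `time`.
#'
#' @param beads A data frame with columns `chain`, `rank`, `x`, `y`, `z`
#'   and optionally `xu`, `yu`, `zu` (defaulting to the wrapped ones).
#' @param box_edge Cubic box edge length (sigma).
#' @param time Simulation time stamp (tau0).
#' @param step Integration step counter matching `time` (used to key the
#'   counter-based RNG across restarts).
#' @return A `polymer_config` tibble.
#' @export
polymer_config <- function(beads, box_edge, time = 0, step = 0) {
  stopifnot(all(c("chain", "rank", "x", "y", "z") %in% names(beads)),
            box_edge > 0)
  beads <- tibble::as_tibble(beads)
  if (!all(c("xu", "yu", "zu") %in% names(beads))) {
    beads$xu <- beads$x
    beads$yu <- beads$y
    beads$zu <- beads$z
  }
  beads <- dplyr::arrange(beads, .data$chain, .data$rank)
  beads <- beads[, c("chain", "rank", "x", "y", "z", "xu", "yu", "zu")]
  beads$chain <- as.integer(beads$chain)
  beads$rank <- as.integer(beads$rank)
  structure(beads,
            box_edge = box_edge, time = time, step = step,
            class = c("polymer_config", class(tibble::tibble())))
}

#' @export
print.polymer_config <- function(x, ...) {
  cat("<polymer_config> ", nrow(x), " beads, ",
      dplyr::n_distinct(x$chain), " chains, box ",
      signif(attr(x, "box_edge"), 6), " sigma, t = ",
      signif(attr(x, "time"), 6), " tau0\n", sep = "")
  NextMethod()
}

#' Accessors for configuration attributes and coordinate matrices
#'
#' @param config A [polymer_config()].
#' @return `box_edge_of`, `time_of` and `step_of` return scalars;
#'   `pos_wrapped` and `pos_unwrapped` return n-by-3 coordinate matrices.
#' @export
box_edge_of <- function(config) attr(config, "box_edge")

#' @rdname box_edge_of
#' @export
time_of <- function(config) attr(config, "time")

#' @rdname box_edge_of
#' @export
step_of <- function(config) attr(config, "step") %||% 0

#' @rdname box_edge_of
#' @export
pos_wrapped <- function(config) {
  cbind(config$x, config$y, config$z)
}

#' @rdname box_edge_of
#' @export
pos_unwrapped <- function(config) {
  cbind(config$xu, config$yu, config$zu)
}

# rebuild a config from new coordinate matrices, keeping chain topology
update_config <- function(config, posW = NULL, posU = NULL, time = NULL,
                          step = NULL) {
  out <- config
  if (!is.null(posW)) {
    out$x <- posW[, 1]; out$y <- posW[, 2]; out$z <- posW[, 3]
  }
  if (!is.null(posU)) {
    out$xu <- posU[, 1]; out$yu <- posU[, 2]; out$zu <- posU[, 3]
  }
  if (!is.null(time)) attr(out, "time") <- time
  if (!is.null(step)) attr(out, "step") <- step
  out
}

#' Build a random-walk melt
#'
#' Places `N` chains of `Np` beads as freely jointed random walks with bond
#' length `0.97 * sigma` (close to the minimum of the combined FENE + WCA
#' bond potential, so the start carries no force spike) in a cubic box
#' whose edge solves the density definition `rho* = N*Np*sigma^3/V`
#' exactly. Overlaps between non-bonded beads are permitted; they are
#' removed afterwards by [soft_pushoff()].
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the same seed reproduces the configuration
#'   bit for bit.
#' @param bond0 Initial bond length (sigma).
#' @return A [polymer_config()] at `time = 0`.
#' @examples
#' p <- sim_params(N = 10, Np = 25, Pe = 0)
#' cfg <- build_random_melt(p, seed = 1)
#' @export
build_random_melt <- function(params, seed = params$seed, bond0 = 0.97) {
  box <- params$box_edge
  if (!is.finite(box) || box <= 0) stop("non-positive box dimension")
  b <- bond0 * params$sigma
  pos <- withr_seed(seed, {
    out <- matrix(0, params$N * params$Np, 3)
    row <- 1L
    for (c in seq_len(params$N)) {
      p <- runif(3, 0, box)
      out[row, ] <- p
      row <- row + 1L
      if (params$Np > 1) {
        for (k in 2:params$Np) {
          p <- p + b * random_unit_vector()
          out[row, ] <- p
          row <- row + 1L
        }
      }
    }
    out
  })
  beads <- tibble::tibble(
    chain = rep(seq_len(params$N), each = params$Np),
    rank = rep(seq_len(params$Np) - 1L, times = params$N),
    x = pos[, 1] - box * floor(pos[, 1] / box),
    y = pos[, 2] - box * floor(pos[, 2] / box),
    z = pos[, 3] - box * floor(pos[, 3] / box),
    xu = pos[, 1], yu = pos[, 2], zu = pos[, 3]
  )
  polymer_config(beads, box_edge = box, time = 0)
}

# evaluate expr under a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) return(v / nv)
  }
}

#' Diagnose the topology of a configuration
#'
#' Report-only check of chain integrity: bond-length extremes, bonds at or
#' beyond the FENE maximum `R0`, broken chains (ranks not running
#' `0..Np-1`), the chain-length histogram, the realised density, and the
#' consistency of wrapped and unwrapped coordinates (they must differ by
#' integer multiples of the box edge).
#'
#' @param config A [polymer_config()].
#' @param params A [sim_params()] object supplying `R0` and `rho_star`.
#' @return A list of class `topology_report`.
#' @export
validate_topology <- function(config, params) {
  box <- box_edge_of(config)
  pu <- pos_unwrapped(config)
  dvec <- diff_bonds(config)
  blen <- sqrt(rowSums(dvec^2))
  chains <- split(config$rank, config$chain)
  broken <- vapply(chains, function(r) !identical(as.integer(r),
                                                  seq_along(r) - 1L),
                   logical(1))
  pw <- pos_wrapped(config)
  imgs <- (pu - pw) / box
  img_ok <- max(abs(imgs - round(imgs))) < 1e-8
  hist_df <- dplyr::count(tibble::tibble(len = unname(lengths(chains))), .data$len,
                          name = "chains")
  rep <- list(
    n_beads = nrow(config),
    n_chains = length(chains),
    bond_min = if (length(blen)) min(blen) else NA_real_,
    bond_max = if (length(blen)) max(blen) else NA_real_,
    n_bond_violations = sum(blen >= params$R0),
    n_broken_chains = sum(broken),
    chain_length_histogram = hist_df,
    density = nrow(config) * params$sigma^3 / box^3,
    images_consistent = img_ok,
    ok = sum(blen >= params$R0) == 0 && !any(broken) && img_ok
  )
  class(rep) <- "topology_report"
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report> ", x$n_beads, " beads / ", x$n_chains, " chains; ",
      "density ", signif(x$density, 6), "\n  bonds in [",
      signif(x$bond_min, 6), ", ", signif(x$bond_max, 6), "]; ",
      x$n_bond_violations, " overstretched, ", x$n_broken_chains,
      " broken chains; ", if (x$ok) "OK" else "VIOLATIONS", "\n", sep = "")
  invisible(x)
}

# bond vectors (unwrapped authority), one row per bond
diff_bonds <- function(config) {
  pu <- pos_unwrapped(config)
  same <- config$chain[-1] == config$chain[-nrow(config)]
  d <- pu[-1, , drop = FALSE] - pu[-nrow(pu), , drop = FALSE]
  d[same, , drop = FALSE]
}

#' Deterministic test-geometry fixtures
#'
#' Analytically specified configurations used to exercise forces and the
#' primitive-path contraction on cases whose answers are known by hand
#' geometry.
#'
#' * `straight_chain`: `Np` beads along +x with given `spacing`.
#' * `hairpin_chain`: a chain that runs `m` beads up +z and folds straight
#'   back onto itself, so exactly one bead has antiparallel adjacent
#'   tangents (used for active-force degeneracy tests; non-bonded beads
#'   coincide, so do not evaluate pair forces on it).
#' * `isolated_pair`: two single-bead chains at separation `r` along a
#'   given direction.
#' * `wrapped_pair`: a straight chain A along x at the origin plus a chain
#'   B whose ends are anchored at `(0, -a, -c)` and `(0, +a, -c)` and whose
#'   contour passes over A at height `apex`; B's shortest non-crossing path
#'   has length `2*sqrt(a^2+c^2)` by unfolding, with one kink at the
#'   contact locus.
#' * `phantom_ideal_chain`: a freely jointed random walk of `Np` beads.
#'
#' @param name Fixture name (see above).
#' @param Np Beads per chain (where applicable).
#' @param spacing Bond spacing (sigma).
#' @param r Separation for `isolated_pair`.
#' @param a,c,apex Geometry of `wrapped_pair` (see above).
#' @param box_edge Box edge; fixtures default to a box large enough that
#'   periodic images play no role.
#' @param seed Seed for `phantom_ideal_chain`.
#' @return A [polymer_config()].
#' @export
make_fixture <- function(name = c("straight_chain", "hairpin_chain",
                                  "isolated_pair", "wrapped_pair",
                                  "phantom_ideal_chain"),
                         Np = 10, spacing = 0.97, r = 1.0,
                         a = 2, c = 1, apex = 1, box_edge = 1000,
                         seed = 1) {
  name <- match.arg(name)
  mk <- function(pos_list) {
    beads <- dplyr::bind_rows(lapply(seq_along(pos_list), function(i) {
      m <- pos_list[[i]]
      tibble::tibble(chain = i, rank = seq_len(nrow(m)) - 1L,
                     x = m[, 1], y = m[, 2], z = m[, 3],
                     xu = m[, 1], yu = m[, 2], zu = m[, 3])
    }))
    # wrap into [0, box)
    for (col in c("x", "y", "z")) {
      beads[[col]] <- beads[[col]] - box_edge * floor(beads[[col]] / box_edge)
    }
    polymer_config(beads, box_edge = box_edge, time = 0)
  }
  if (name == "straight_chain") {
    m <- cbind((seq_len(Np) - 1) * spacing, 0, 0)
    return(mk(list(m)))
  }
  if (name == "hairpin_chain") {
    stopifnot(Np >= 3)
    m_up <- ceiling(Np / 2)
    zs <- c(seq_len(m_up) - 1, rev(seq_len(Np - m_up)) - 1) * spacing
    m <- cbind(0, 0, zs)
    return(mk(list(m)))
  }
  if (name == "isolated_pair") {
    return(mk(list(matrix(c(0, 0, 0), 1), matrix(c(r, 0, 0), 1))))
  }
  if (name == "wrapped_pair") {
    # chain A: straight along x, centred on the origin
    nA <- Np
    xa <- (seq_len(nA) - (nA + 1) / 2) * spacing
    A <- cbind(xa, 0, 0)
    # chain B (also Np beads): piecewise-linear arc from (0,-a,-c) over
    # (0,0,apex) to (0,a,-c)
    m1 <- ceiling((Np + 1) / 2)
    m2 <- Np - m1
    t1 <- seq(0, 1, length.out = m1)
    up <- cbind(0, -a + t1 * a, -c + t1 * (c + apex))
    t2 <- seq(0, 1, length.out = m2 + 1)[-1]
    dn <- cbind(0, t2 * a, apex - t2 * (c + apex))
    B <- rbind(up, dn)
    return(mk(list(A, B)))
  }
  # phantom_ideal_chain
  m <- withr_seed(seed, {
    steps <- t(vapply(seq_len(Np - 1), function(i) random_unit_vector(),
                      numeric(3))) * spacing
    cs <- apply(steps, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
    rbind(c(0, 0, 0), cs)
  })
  offset <- box_edge / 2
  mk(list(m + offset))
}
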