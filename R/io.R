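fmt_num <- function(x) sprintf("%.10g", x)

#' Write configurations as extended XYZ
#'
#' One frame per configuration: an atom-count line, a comment line
#' carrying the cubic lattice, the column schema, the time stamp and a
#' provenance tag, then one row per bead with wrapped position, chain id,
#' bead rank and integer image flags (so the unwrapped position is
#' recovered exactly to the written precision).
#'
#' @param configs A [polymer_config()] or list of them.
#' @param path Output file.
#' @param provenance Named character vector folded into the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(configs, path, provenance = character()) {
  if (inherits(configs, "polymer_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    box <- box_edge_of(cfg)
    img <- round((pos_unwrapped(cfg) - pos_wrapped(cfg)) / box)
    extra <- if (length(provenance)) {
      paste0(" ", paste0(names(provenance), "=\"", provenance, "\"",
                         collapse = " "))
    } else ""
    writeLines(as.character(nrow(cfg)), con)
    writeLines(paste0(
      "Lattice=\"", fmt_num(box), " 0 0 0 ", fmt_num(box), " 0 0 0 ",
      fmt_num(box), "\" ",
      "Properties=species:S:1:pos:R:3:chain:I:1:rank:I:1:image:I:3 ",
      "Time=", fmt_num(time_of(cfg)), " Step=", fmt_num(step_of(cfg)),
      extra), con)
    writeLines(paste("A", fmt_num(cfg$x), fmt_num(cfg$y), fmt_num(cfg$z),
                     cfg$chain, cfg$rank,
                     img[, 1], img[, 2], img[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path File written by [write_xyz()] (or compatible).
#' @return List of [polymer_config()] frames.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nframe <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) {
      stop("malformed frame header at line ", i, " (after ", nframe,
           " complete frames)")
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated file: frame ", nframe + 1L, " incomplete; last ",
           "complete frame is ", nframe)
    }
    comment <- lines[i + 1L]
    lat <- regmatches(comment,
                      regexpr("Lattice=\"[^\"]+\"", comment))
    if (!length(lat)) stop("frame ", nframe + 1L, ": missing Lattice")
    latv <- as.numeric(strsplit(gsub("Lattice=\"|\"", "", lat), "\\s+")[[1]])
    box <- latv[1]
    gettag <- function(tag, default = 0) {
      m <- regmatches(comment, regexpr(paste0(tag, "=[^ ]+"), comment))
      if (!length(m)) return(default)
      as.numeric(sub(paste0(tag, "="), "", m))
    }
    tm <- gettag("Time")
    stp <- gettag("Step")
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 9)
    if (length(bad)) {
      stop("malformed atom line at line ", i + 1L + bad[1],
           " in frame ", nframe + 1L)
    }
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:9))),
                ncol = 8, byrow = TRUE)
    beads <- tibble::tibble(
      chain = as.integer(m[, 4]), rank = as.integer(m[, 5]),
      x = m[, 1], y = m[, 2], z = m[, 3],
      xu = m[, 1] + m[, 6] * box, yu = m[, 2] + m[, 7] * box,
      zu = m[, 3] + m[, 8] * box)
    nframe <- nframe + 1L
    frames[[nframe]] <- polymer_config(beads, box_edge = box, time = tm,
                                       step = stp)
    if (nframe > 1 &&
        abs(box - box_edge_of(frames[[1]])) > 1e-9 * box) {
      stop("box mismatch across frames (frame ", nframe, ")")
    }
    i <- i + 2L + n
  }
  frames
}

#' Write configurations in the LAMMPS dump dialect
#'
#' `ITEM: ATOMS id mol type x y z ix iy iz` with a periodic cubic box;
#' time is carried on an `ITEM: TIME` record.
#'
#' @inheritParams write_xyz
#' @export
write_lammps_dump <- function(configs, path) {
  if (inherits(configs, "polymer_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    box <- box_edge_of(cfg)
    img <- round((pos_unwrapped(cfg) - pos_wrapped(cfg)) / box)
    writeLines(c("ITEM: TIMESTEP", fmt_num(step_of(cfg)),
                 "ITEM: TIME", fmt_num(time_of(cfg)),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(cfg)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste("0", fmt_num(box)), paste("0", fmt_num(box)),
                 paste("0", fmt_num(box)),
                 "ITEM: ATOMS id mol type x y z ix iy iz"), con)
    writeLines(paste(seq_len(nrow(cfg)), cfg$chain, 1L,
                     fmt_num(cfg$x), fmt_num(cfg$y), fmt_num(cfg$z),
                     img[, 1], img[, 2], img[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Accepts both wrapped columns with image flags (`x y z ix iy iz`) and
#' unwrapped columns (`xu yu zu`), for which image flags are
#' reconstructed. Bead ranks are assigned by atom id order within each
#' molecule.
#'
#' @param path Dump file.
#' @return List of [polymer_config()] frames.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nframe <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) {
      stop("expected ITEM: TIMESTEP at line ", i, " (after ", nframe,
           " complete frames)")
    }
    stp <- as.numeric(lines[i + 1L])
    i <- i + 2L
    tm <- stp
    if (i <= length(lines) && startsWith(lines[i], "ITEM: TIME")) {
      tm <- as.numeric(lines[i + 1L])
      i <- i + 2L
    }
    if (!startsWith(lines[i], "ITEM: NUMBER OF ATOMS")) {
      stop("expected ITEM: NUMBER OF ATOMS at line ", i)
    }
    n <- as.integer(lines[i + 1L])
    i <- i + 2L
    if (!startsWith(lines[i], "ITEM: BOX BOUNDS")) {
      stop("expected ITEM: BOX BOUNDS at line ", i)
    }
    b <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]])
    box <- b[2] - b[1]
    i <- i + 4L
    if (!startsWith(lines[i], "ITEM: ATOMS")) {
      stop("expected ITEM: ATOMS at line ", i)
    }
    cols <- strsplit(sub("ITEM: ATOMS ", "", lines[i]), "\\s+")[[1]]
    if (i + n > length(lines)) {
      stop("truncated file: frame ", nframe + 1L, " incomplete; last ",
           "complete frame is ", nframe)
    }
    body <- lines[(i + 1L):(i + n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                nrow = n, byrow = TRUE)
    colnames(m) <- cols
    ord <- order(m[, "mol"], m[, "id"])
    m <- m[ord, , drop = FALSE]
    if (all(c("xu", "yu", "zu") %in% cols)) {
      xu <- m[, "xu"]; yu <- m[, "yu"]; zu <- m[, "zu"]
      x <- xu - box * floor(xu / box)
      y <- yu - box * floor(yu / box)
      z <- zu - box * floor(zu / box)
    } else if (all(c("x", "y", "z") %in% cols)) {
      x <- m[, "x"]; y <- m[, "y"]; z <- m[, "z"]
      if (all(c("ix", "iy", "iz") %in% cols)) {
        xu <- x + m[, "ix"] * box
        yu <- y + m[, "iy"] * box
        zu <- z + m[, "iz"] * box
      } else {
        xu <- x; yu <- y; zu <- z
      }
    } else {
      stop("dump frame ", nframe + 1L,
           ": need x y z [ix iy iz] or xu yu zu columns")
    }
    mol <- as.integer(m[, "mol"])
    rank <- stats::ave(seq_along(mol), mol, FUN = seq_along) - 1L
    beads <- tibble::tibble(chain = mol, rank = as.integer(rank),
                            x = x, y = y, z = z, xu = xu, yu = yu, zu = zu)
    nframe <- nframe + 1L
    frames[[nframe]] <- polymer_config(beads, box_edge = box, time = tm,
                                       step = stp)
    i <- i + n + 1L
  }
  frames
}

#' Write a stress time series
#'
#' Columnar text: provenance header lines starting with `#`, a column
#' header, then `time sxx syy szz sxy sxz syz volume` rows at `%.10g`.
#'
#' @param stress Stress tibble (as produced by [bd_run()]).
#' @param path Output file.
#' @param provenance Named character vector written into the header.
#' @export
write_stress <- function(stress, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# actipoly-stress-v1", con)
  for (k in names(provenance)) {
    writeLines(paste0("# ", k, ": ", provenance[[k]]), con)
  }
  writeLines("# time sxx syy szz sxy sxz syz volume", con)
  writeLines(do.call(paste, lapply(stress[, c("time", "sxx", "syy", "szz",
                                              "sxy", "sxz", "syz",
                                              "volume")], fmt_num)), con)
  invisible(path)
}

#' Read a stress time series written by [write_stress()]
#' @param path Stress file.
#' @return Stress tibble with attribute `header` (the provenance lines).
#' @export
read_stress <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              ncol = 8, byrow = TRUE)
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- c("time", "sxx", "syy", "szz", "sxy", "sxz", "syz",
                  "volume")
  attr(out, "header") <- hdr
  out
}

#' Read and validate a run-configuration file
#'
#' YAML with a versioned schema (`schema: actipoly-run-v1`), a `params`
#' block (fields of [sim_params()]; exactly one of `Pe`/`Fp`), a
#' `schedule` block (fields of [run_schedule()]) and an optional
#' `equilibration` block. Unknown keys anywhere are rejected.
#'
#' @param path YAML file.
#' @return List with `params` (a `sim_params`), `schedule` (a
#'   `run_schedule`) and `equilibration` (a list of overrides).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 implicit typing turns a bare `N` key into the boolean FALSE;
  # map it back (it is the only such key in the schema)
  for (blk in c("params", "schedule", "equilibration")) {
    nm <- names(cfg[[blk]])
    if (!is.null(nm)) names(cfg[[blk]]) <- ifelse(nm == "FALSE", "N", nm)
  }
  known_top <- c("schema", "params", "schedule", "equilibration")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    stop("unknown top-level keys: ", paste(unknown, collapse = ", "))
  }
  if (!identical(cfg$schema, "actipoly-run-v1")) {
    stop("unsupported or missing schema (need actipoly-run-v1)")
  }
  pk <- c("N", "Np", "Pe", "Fp", "rho_star", "sigma", "kBT", "zeta",
          "eps_wca", "eps_fene", "R0", "kappa", "dt", "seed")
  unknown <- setdiff(names(cfg$params), pk)
  if (length(unknown)) {
    stop("unknown params keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$params$Pe) && !is.null(cfg$params$Fp)) {
    stop("config sets both Pe and Fp; give exactly one")
  }
  params <- do.call(sim_params, cfg$params)
  sk <- c("n_steps", "stride_stress", "stride_config", "stride_log",
          "steady_state_time", "stride_bond")
  unknown <- setdiff(names(cfg$schedule), sk)
  if (length(unknown)) {
    stop("unknown schedule keys: ", paste(unknown, collapse = ", "))
  }
  schedule <- do.call(run_schedule, cfg$schedule)
  ek <- c("bd_steps", "sweeps", "min_blocks", "max_blocks", "tol")
  unknown <- setdiff(names(cfg$equilibration), ek)
  if (length(unknown)) {
    stop("unknown equilibration keys: ", paste(unknown, collapse = ", "))
  }
  list(params = params, schedule = schedule,
       equilibration = cfg$equilibration %||% list())
}
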