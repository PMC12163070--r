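#' End-to-end simulation and analysis pipeline
#'
#' Runs build -> soft push-off -> equilibration -> production ->
#' rheology + primitive-path analysis, writing each stage's artifact and
#' a master manifest (parameters, seed, stage list, file checksums) so
#' any stage can be re-run from its predecessor's output. Stages whose
#' artifact already exists are skipped when `resume = TRUE`.
#'
#' @param config A list from [read_run_config()], or a path to a run
#'   configuration file.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the seed in the configuration.
#' @param resume Skip stages whose artifact already exists.
#' @return The manifest (also written to `manifest.json`), invisibly a
#'   list with file paths and stage summaries.
#' @export
pipeline <- function(config, out_dir = ".", seed = NULL, resume = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  params <- config$params
  if (!is.null(seed)) params$seed <- as.integer(seed)
  schedule <- config$schedule
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pt <- function(f) file.path(out_dir, f)
  stages <- list()
  prov <- c(package = "actipoly",
            version = as.character(utils::packageVersion("actipoly")),
            seed = as.character(params$seed))

  run_stage <- function(name, artifact, fn) {
    if (resume && file.exists(pt(artifact))) {
      stages[[name]] <<- list(name = name, artifact = artifact,
                              status = "resumed")
      return(invisible(NULL))
    }
    fn()
    stages[[name]] <<- list(name = name, artifact = artifact,
                            status = "completed")
    invisible(NULL)
  }

  cfg <- NULL
  run_stage("build", "initial.xyz", function() {
    cfg <<- build_random_melt(params, seed = params$seed)
    write_xyz(cfg, pt("initial.xyz"), provenance = prov)
  })
  if (is.null(cfg)) cfg <- read_xyz(pt("initial.xyz"))[[1]]

  run_stage("pushoff", "pushed.xyz", function() {
    cfg <<- soft_pushoff(cfg, params, seed = params$seed)
    write_xyz(cfg, pt("pushed.xyz"), provenance = prov)
  })
  if (stages$pushoff$status == "resumed") cfg <- read_xyz(pt("pushed.xyz"))[[1]]

  run_stage("equilibrate", "equilibrated.xyz", function() {
    eqargs <- c(list(cfg, params, seed = params$seed),
                config$equilibration)
    eq <- do.call(equilibrate, eqargs)
    cfg <<- eq$config
    write_xyz(cfg, pt("equilibrated.xyz"), provenance = prov)
    jsonlite::write_json(
      list(converged = eq$converged, history = eq$history, msid = eq$msid),
      pt("equilibration_report.json"), auto_unbox = TRUE, digits = NA)
  })
  if (stages$equilibrate$status == "resumed") {
    cfg <- read_xyz(pt("equilibrated.xyz"))[[1]]
  }

  run <- NULL
  run_stage("production", "stress.dat", function() {
    run <<- bd_run(cfg, params, schedule, seed = params$seed)
    write_stress(run$stress, pt("stress.dat"), provenance = c(
      prov, Pe = as.character(params$Pe), L = as.character(params$L),
      active_virial = "included"))
    if (!is.null(run$trajectory)) {
      write_xyz(trajectory_configs(run), pt("traj.xyz"), provenance = prov)
    }
    write_xyz(run$config, pt("final.xyz"), provenance = prov)
  })

  run_stage("analysis", "rheology.json", function() {
    stress <- if (!is.null(run)) run$stress else read_stress(pt("stress.dat"))
    corr <- accumulate_g(stress, kBT = params$kBT)
    fit <- fit_plateau_and_tau(corr)
    eta <- green_kubo_eta(corr)
    jsonlite::write_json(list(
      G = corr[, c("lag", "G", "count")],
      fit = unclass(glance(fit)), G0 = fit$G0, tau_eff = fit$tau_eff,
      eta_inf = eta_inf(eta),
      tau_eff_interpolation = tau_eff_prediction(params$L, params$v,
                                                 params$D0, params$sigma)
    ), pt("rheology.json"), auto_unbox = TRUE, digits = NA)
    final <- if (!is.null(run)) run$config else read_xyz(pt("final.xyz"))[[1]]
    ppa <- ppa_contract(final)
    jsonlite::write_json(list(
      chains = ppa$chains, Ne = ppa$Ne, converged = ppa$converged
    ), pt("ppa.json"), auto_unbox = TRUE, digits = NA)
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest.json$", files)]
  manifest <- list(
    schema = "actipoly-manifest-v1",
    seed = params$seed,
    params = unclass(tidy(params)),
    stages = unname(stages),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, pt("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
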