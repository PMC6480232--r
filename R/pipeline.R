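# Orchestration: each subcommand reads its inputs from the run directory,
# writes CSV / ESRI-ASCII artifacts plus a run log, and stamps everything
# with the md5 of the normalised configuration so artifacts from different
# configurations cannot be mixed.

#' Default run configuration
#'
#' @param outdir run directory for all artifacts.
#' @param seed single seed from which all randomness in the run derives.
#' @return named list; see the commented example written by
#'   [write_example_config()].
#' @export
default_config <- function(outdir = "plumekrig_run", seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    mode = "annual",            # annual | monthly-pooled | per-month
    n_receptors = 20,
    n_hours = 900,
    calm_frac = 0.2,
    noise_sd = 0.15,
    ustar_min = 0.1,
    sigma_z0 = 10,
    grid_res = 1000,
    bootstrap_B = 1000,
    sigma_z0_sweep = c(0, 5, 10, 20, 50),
    variogram_family = "exponential",
    domain = c(40000, 80000)
  )
}

#' Write a commented example configuration file
#'
#' @param path output YAML path.
#' @export
write_example_config <- function(path) {
  writeLines(c(
    "# plumekrig run configuration",
    "# outdir: all artifacts are written here",
    "# seed: every random draw in the run derives from this one seed",
    "# mode: annual | monthly-pooled | per-month fitting",
    "# grid_res: map grid resolution in meters",
    yaml::as.yaml(default_config())), path)
  invisible(path)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$grid_res > 0)
  cfg
}

.config_md5 <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  core <- cfg[setdiff(names(cfg), "outdir")]
  yaml::write_yaml(core[order(names(core))], f)
  unname(tools::md5sum(f))
}

.check_provenance <- function(meta_path, md5, prerequisite) {
  if (!file.exists(meta_path)) {
    stop("missing upstream artifact ", meta_path,
         "; run the '", prerequisite, "' subcommand first")
  }
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$config_md5, md5)) {
    stop("artifact ", meta_path, " was produced under a different ",
         "configuration (hash ", meta$config_md5, " vs ", md5,
         "); refusing to mix provenance")
  }
  meta
}

.log_line <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " INFO ", ...)
  cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
  message(msg)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic scenario: met, sources,
#' receptors, observations, true rates), `build-transfer` (unit-emission
#' transfer matrix), `invert` (non-negative fit of category rates),
#' `bootstrap` (95% CIs), `map` (model field, residual-kriging and
#' simple-kriging maps as ESRI ASCII grids), `evaluate` (performance report
#' + leave-one-out cross-validation), `sweep` (rates vs initial vertical
#' plume spread). Artifacts are CSV/ASCII in `config$outdir`; each stage
#' checks that its inputs carry the same configuration hash.
#'
#' @param subcommand one of the above.
#' @param config configuration list or YAML path (see [default_config()]).
#' @return invisibly, the paths of the artifacts written.
#' @export
run_pipeline <- function(subcommand = c("simulate", "build-transfer",
                                        "invert", "bootstrap", "map",
                                        "evaluate", "sweep"),
                         config = default_config()) {
  subcommand <- match.arg(subcommand)
  cfg <- .load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  md5 <- .config_md5(cfg)
  pth <- function(...) file.path(cfg$outdir, ...)
  meta <- function(name, extra = list()) {
    yaml::write_yaml(c(list(config_md5 = md5, version =
                              as.character(utils::packageVersion("plumekrig"))),
                      extra), pth(paste0(name, ".meta.yaml")))
  }
  written <- character(0)

  if (subcommand == "simulate") {
    sc <- valley_scenario(seed = cfg$seed, n_receptors = cfg$n_receptors,
                          n_hours = cfg$n_hours, calm_frac = cfg$calm_frac,
                          domain = cfg$domain,
                          sigma_z0_border = cfg$sigma_z0)
    utils::write.csv(as.data.frame(sc$met), pth("met.csv"), row.names = FALSE)
    write_sources(sc$sources, pth("sources.csv"))
    utils::write.csv(sc$receptors, pth("receptors.csv"), row.names = FALSE)
    tm <- build_transfer_matrix(sc$sources, sc$receptors, sc$met,
                                ustar_min = cfg$ustar_min)
    write_transfer_matrix(tm, pth("transfer_matrix.csv"), config_md5 = md5)
    c_obs <- make_observations(tm, sc$E_true, noise_sd = cfg$noise_sd,
                               seed = cfg$seed + 2L)
    utils::write.csv(data.frame(receptor_id = sc$receptors$id, pm25 = c_obs),
                     pth("observations.csv"), row.names = FALSE)
    utils::write.csv(data.frame(category = names(sc$E_true),
                                rate = unname(sc$E_true)),
                     pth("true_rates.csv"), row.names = FALSE)
    meta("scenario", list(n_hours = nrow(sc$met),
                          n_non_calm = tm$n_hours_used,
                          n_receptors = nrow(sc$receptors)))
    .log_line(cfg$outdir, "simulate: ", nrow(sc$met), " hours (",
              tm$n_hours_used, " non-calm), ", nrow(sc$receptors),
              " receptors, seed ", cfg$seed)
    written <- pth(c("met.csv", "sources.csv", "receptors.csv",
                     "observations.csv", "true_rates.csv",
                     "transfer_matrix.csv"))
  } else if (subcommand == "build-transfer") {
    .check_provenance(pth("scenario.meta.yaml"), md5, "simulate")
    met <- read_surface_met(pth("met.csv"))
    sources <- read_sources(pth("sources.csv"))
    rec <- utils::read.csv(pth("receptors.csv"), stringsAsFactors = FALSE)
    tm <- build_transfer_matrix(sources, rec, met, ustar_min = cfg$ustar_min)
    write_transfer_matrix(tm, pth("transfer_matrix.csv"), config_md5 = md5)
    .log_line(cfg$outdir, "build-transfer: ", tm$n_hours_used,
              " non-calm hours averaged")
    written <- pth("transfer_matrix.csv")
  } else if (subcommand == "invert") {
    tm <- read_transfer_matrix(pth("transfer_matrix.csv"))
    .check_provenance(pth("transfer_matrix.csv.meta.yaml"), md5,
                      "simulate or build-transfer")
    obs <- utils::read.csv(pth("observations.csv"), stringsAsFactors = FALSE)
    fit <- nnls_fit(tm, obs$pm25)
    utils::write.csv(data.frame(category = names(fit$rates),
                                rate = unname(fit$rates)),
                     pth("rates.csv"), row.names = FALSE)
    utils::write.csv(data.frame(receptor_id = tm$receptors,
                                observed = obs$pm25, fitted = fit$fitted,
                                residual = fit$residuals),
                     pth("residuals.csv"), row.names = FALSE)
    meta("rates", list(objective = fit$objective, kkt_ok = fit$kkt_ok))
    .log_line(cfg$outdir, "invert: rates ",
              paste(names(fit$rates), round(fit$rates, 2), collapse = ", "))
    written <- pth(c("rates.csv", "residuals.csv"))
  } else if (subcommand == "bootstrap") {
    tm <- read_transfer_matrix(pth("transfer_matrix.csv"))
    .check_provenance(pth("transfer_matrix.csv.meta.yaml"), md5,
                      "simulate or build-transfer")
    obs <- utils::read.csv(pth("observations.csv"), stringsAsFactors = FALSE)
    bs <- bootstrap_ci(tm, obs$pm25, B = cfg$bootstrap_B,
                       seed = cfg$seed + 3L)
    utils::write.csv(bs$ci, pth("rates_ci.csv"), row.names = FALSE)
    .log_line(cfg$outdir, "bootstrap: B = ", bs$B, ", seed ", cfg$seed + 3L)
    written <- pth("rates_ci.csv")
  } else if (subcommand == "map") {
    .check_provenance(pth("rates.meta.yaml"), md5, "invert")
    met <- read_surface_met(pth("met.csv"))
    sources <- read_sources(pth("sources.csv"))
    rec <- utils::read.csv(pth("receptors.csv"), stringsAsFactors = FALSE)
    obs <- utils::read.csv(pth("observations.csv"), stringsAsFactors = FALSE)
    rates_df <- utils::read.csv(pth("rates.csv"), stringsAsFactors = FALSE)
    rates <- stats::setNames(rates_df$rate, rates_df$category)
    gs <- grid_spec(0, cfg$domain[1], 0, cfg$domain[2], res = cfg$grid_res)
    mf <- model_grid_field(sources, rates, met, gs)
    tm <- read_transfer_matrix(pth("transfer_matrix.csv"))
    model_rec <- as.numeric(tm$values[, names(rates), drop = FALSE] %*% rates)
    rk <- residual_krige_map(mf, rec, obs$pm25,
                             family = cfg$variogram_family,
                             model_at_receptors = model_rec)
    sk <- simple_krige_map(rec, obs$pm25, gs, family = cfg$variogram_family)
    write_asc(mf, pth("model_field.asc"), csv = TRUE)
    write_asc(rk, pth("map_residual_kriging.asc"), csv = TRUE)
    write_asc(sk, pth("map_simple_kriging.asc"), csv = TRUE)
    utils::write.csv(attr(rk, "residuals"), pth("map_residuals.csv"),
                     row.names = FALSE)
    meta("map", list(grid_res = cfg$grid_res,
                     n_nodes = length(gs$gx) * length(gs$gy),
                     n_floored = attr(rk, "n_floored")))
    .log_line(cfg$outdir, "map: ", length(gs$gx), "x", length(gs$gy),
              " nodes at ", cfg$grid_res, " m; floored ",
              attr(rk, "n_floored"), " node(s)")
    written <- pth(c("model_field.asc", "map_residual_kriging.asc",
                     "map_simple_kriging.asc", "map_residuals.csv"))
  } else if (subcommand == "evaluate") {
    .check_provenance(pth("rates.meta.yaml"), md5, "invert")
    res <- utils::read.csv(pth("residuals.csv"), stringsAsFactors = FALSE)
    rec <- utils::read.csv(pth("receptors.csv"), stringsAsFactors = FALSE)
    rep_ <- performance_report(res$observed, res$fitted)
    utils::write.csv(rep_, pth("report.csv"), row.names = FALSE)
    cv <- loocv_compare(rec, res$observed, res$fitted,
                        family = cfg$variogram_family)
    utils::write.csv(cv$table, pth("loocv.csv"), row.names = FALSE)
    .log_line(cfg$outdir, "evaluate: fraction within 2 = ",
              round(rep_$fraction_within_2, 3), ", sg = ", round(rep_$sg, 3),
              ", LOOCV r2 simple = ", round(cv$r2_simple, 3),
              ", residual = ", round(cv$r2_residual, 3))
    written <- pth(c("report.csv", "loocv.csv"))
  } else if (subcommand == "sweep") {
    .check_provenance(pth("scenario.meta.yaml"), md5, "simulate")
    met <- read_surface_met(pth("met.csv"))
    sources <- read_sources(pth("sources.csv"))
    rec <- utils::read.csv(pth("receptors.csv"), stringsAsFactors = FALSE)
    obs <- utils::read.csv(pth("observations.csv"), stringsAsFactors = FALSE)
    sw <- sigma_z0_sweep(sources, rec, met, obs$pm25, cfg$sigma_z0_sweep)
    utils::write.csv(sw$table, pth("sweep.csv"), row.names = FALSE)
    .log_line(cfg$outdir, "sweep: sigma_z0 values ",
              paste(cfg$sigma_z0_sweep, collapse = ", "))
    written <- pth("sweep.csv")
  }
  invisible(written)
}
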