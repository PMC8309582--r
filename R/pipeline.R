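# Pipeline orchestration: a structured YAML config drives each stage
# (simulate, calibrate, variogram, fit, evaluate, map), writing CSV /
# YAML artefacts into the configured output directory. The thin
# command-line wrapper in inst/cli/stkrige calls run_stage() and maps
# config errors to exit code 2 and runtime errors to exit code 1.

.CONFIG_SCHEMA <- list(
  output_dir = NULL, seed = NULL,
  simulate = c("n_days", "day_start", "day_hours", "sampling_interval",
               "base", "amplitude", "peak_hour", "family", "sill", "nugget",
               "range", "K", "noise_sd", "station_x", "station_y", "cap"),
  calibrate = c("observations", "station"),
  variogram = c("n_spatial_bins", "n_temporal_bins", "max_spatial_lag",
                "max_temporal_lag", "directional"),
  fit = c("families", "n_starts"),
  evaluate = c("methods", "scenarios", "fractions", "k", "n_max",
               "segment_mean", "segment_sd", "idw_c"),
  map = c("method", "n_x", "n_y", "cell_size", "times_hours", "n_max",
          "rasters")
)

#' Default pipeline configuration
#'
#' Every stage default lives here; [run_stage()] deep-merges a user
#' config (and overrides) on top of it.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    output_dir = "stkrige_out",
    seed = 1L,
    simulate = list(n_days = 2, day_start = 7, day_hours = 10,
                    sampling_interval = 40, base = 45, amplitude = 25,
                    peak_hour = 14, family = "exponential", sill = 60,
                    nugget = 2, range = 20000, K = 100, noise_sd = 1,
                    station_x = 0, station_y = 0, cap = 8000),
    calibrate = list(observations = NULL, station = NULL),
    variogram = list(n_spatial_bins = 12, n_temporal_bins = 12,
                     max_spatial_lag = NULL, max_temporal_lag = 600,
                     directional = TRUE),
    fit = list(families = "auto", n_starts = 8),
    evaluate = list(methods = c("sk", "ok", "ked", "idw"),
                    scenarios = c("random_points", "path_segments",
                                  "leave_line_out"),
                    fractions = c(0.2, 0.4, 0.6, 0.8), k = 4, n_max = 50,
                    segment_mean = 20, segment_sd = 10, idw_c = NULL),
    map = list(method = "ked", n_x = 50, n_y = 50, cell_size = NULL,
               times_hours = NULL, n_max = 50, rasters = FALSE)
  )
}

#' Read and validate a pipeline configuration
#'
#' Unknown keys anywhere in the file are a config error naming them.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return The validated config merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop_stkrige("stkrige_config_error",
                                         paste0("no such config: ", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else stop_stkrige("stkrige_config_error", "config must be a path or list")
  .validate_config(user)
  .merge_config(default_config(), user)
}

.validate_config <- function(user) {
  bad <- setdiff(names(user), names(.CONFIG_SCHEMA))
  for (section in intersect(names(user), names(.CONFIG_SCHEMA))) {
    allowed <- .CONFIG_SCHEMA[[section]]
    if (!is.null(allowed) && is.list(user[[section]])) {
      bad <- c(bad, paste0(section, ".",
                           setdiff(names(user[[section]]), allowed)))
    }
  }
  bad <- bad[!grepl("\\.$", bad)]
  if (length(bad)) {
    stop_stkrige("stkrige_config_error",
                 paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

.cfg_paths <- function(cfg) {
  d <- cfg$output_dir
  list(obs = cfg$calibrate$observations %||% file.path(d, "observations.csv"),
       station = cfg$calibrate$station %||% file.path(d, "station.csv"),
       calibrated = file.path(d, "calibrated.csv"),
       calibration = file.path(d, "calibration.csv"),
       models = file.path(d, "models.yaml"),
       cv = file.path(d, "cv_report.csv"),
       map = file.path(d, "map.csv"))
}

#' Run one pipeline stage
#'
#' @param stage One of `"simulate"`, `"calibrate"`, `"variogram"`,
#'   `"fit"`, `"evaluate"`, `"map"`.
#' @param config Path to a YAML config, or a named list; merged over
#'   [default_config()].
#' @param overrides Named list merged on top of the config (validated
#'   the same way).
#' @return Invisible list of artefact paths written by the stage.
#' @export
run_stage <- function(stage = c("simulate", "calibrate", "variogram", "fit",
                                "evaluate", "map"),
                      config = list(), overrides = list()) {
  stage <- tryCatch(match.arg(stage), error = function(e)
    stop_stkrige("stkrige_config_error", paste0("unknown stage: ", stage[1])))
  cfg <- read_config(config)
  .validate_config(overrides)
  cfg <- .merge_config(cfg, overrides)
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  p <- .cfg_paths(cfg)
  t0 <- proc.time()[["elapsed"]]
  out <- switch(stage,
    simulate = .stage_simulate(cfg, p),
    calibrate = .stage_calibrate(cfg, p),
    variogram = .stage_variogram(cfg, p),
    fit = .stage_fit(cfg, p),
    evaluate = .stage_evaluate(cfg, p),
    map = .stage_map(cfg, p))
  log_event(stage, "done", elapsed_s = sprintf("%.1f", proc.time()[["elapsed"]] - t0))
  invisible(out)
}

#' Run several pipeline stages in order
#'
#' @inheritParams run_stage
#' @param stages Character vector of stages, executed in the given order.
#' @return Invisible list of artefact paths per stage.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "calibrate", "variogram",
                                    "fit", "evaluate"),
                         overrides = list()) {
  invisible(lapply(stages, run_stage, config = config, overrides = overrides))
}

.stage_simulate <- function(cfg, p) {
  s <- cfg$simulate
  camp <- simulate_campaign(
    routes = .default_routes(s$sampling_interval),
    field = field_spec(s$base, s$amplitude, s$peak_hour,
                       variogram_model(s$family, s$sill, s$nugget, s$range, s$K)),
    faults = NULL, n_days = s$n_days, day_start = s$day_start,
    day_hours = s$day_hours, station_pos = c(s$station_x, s$station_y),
    seed = cfg$seed, cap = s$cap)
  camp$faults$noise_sd <- s$noise_sd   # noise level is a config knob
  camp$raw$obs$value <- corrupt_sensors(camp$truth$obs$value,
                                        camp$truth$obs$sensor_id,
                                        camp$faults, seed = cfg$seed)
  write_campaign(camp, cfg$output_dir)
  log_event("simulate", "campaign_written", n = n_obs(camp$raw))
  list(observations = p$obs, station = p$station,
       truth = file.path(cfg$output_dir, "truth.csv"))
}

.stage_calibrate <- function(cfg, p) {
  raw <- read_observations(p$obs)
  station <- read_station(p$station)
  cal <- calibrate_sensors(raw, station)
  write_calibration(cal, p$calibration)
  write_observations(apply_calibration(raw, cal), p$calibrated)
  log_event("calibrate", "fitted", sensors = nrow(cal))
  list(calibration = p$calibration, calibrated = p$calibrated)
}

.stage_variogram <- function(cfg, p) {
  v <- cfg$variogram
  obs <- read_observations(p$calibrated)
  station <- read_station(p$station)
  emp <- empirical_variogram(obs, v$n_spatial_bins, v$n_temporal_bins,
                             v$max_spatial_lag, v$max_temporal_lag)
  files <- file.path(cfg$output_dir, "variogram.csv")
  write_empirical_variogram(emp, files)
  res <- empirical_variogram(station_residuals(obs, station),
                             v$n_spatial_bins, v$n_temporal_bins,
                             v$max_spatial_lag, v$max_temporal_lag)
  f2 <- file.path(cfg$output_dir, "variogram_residuals.csv")
  write_empirical_variogram(res, f2)
  files <- c(files, f2)
  if (isTRUE(v$directional)) {
    dirs <- directional_variograms(obs, v$n_spatial_bins, v$n_temporal_bins,
                                   v$max_spatial_lag, v$max_temporal_lag)
    for (ax in names(dirs)) {
      f <- file.path(cfg$output_dir, sprintf("variogram_%s.csv", ax))
      write_empirical_variogram(dirs[[ax]], f)
      files <- c(files, f)
    }
  }
  files
}

.stage_fit <- function(cfg, p) {
  v <- cfg$variogram
  obs <- read_observations(p$calibrated)
  station <- read_station(p$station)
  fam <- cfg$fit$families
  if (!identical(fam, "auto")) fam <- unlist(fam)
  models <- fit_method_models(obs, station, families = fam,
                              seed = cfg$seed, n_starts = cfg$fit$n_starts,
                              n_spatial_bins = v$n_spatial_bins,
                              n_temporal_bins = v$n_temporal_bins,
                              max_spatial_lag = v$max_spatial_lag,
                              max_temporal_lag = v$max_temporal_lag)
  write_variogram_models(models, p$models)
  list(models = p$models)
}

.stage_evaluate <- function(cfg, p) {
  e <- cfg$evaluate
  obs <- read_observations(p$calibrated)
  station <- read_station(p$station)
  models <- read_variogram_models(p$models)
  day <- campaign_day(obs, cfg$simulate$n_days - 1)
  rep <- cross_validate(day, station, models, methods = e$methods,
                        scenarios = e$scenarios, fractions = e$fractions,
                        k = e$k, seed = cfg$seed, idw_c = e$idw_c,
                        n_max = e$n_max, segment_mean = e$segment_mean,
                        segment_sd = e$segment_sd)
  write_cv_report(rep, p$cv)
  list(cv = p$cv, summary = sub("\\.csv$", "_summary.csv", p$cv))
}

.stage_map <- function(cfg, p) {
  m <- cfg$map
  obs <- read_observations(p$calibrated)
  station <- read_station(p$station)
  models <- read_variogram_models(p$models)
  day <- cfg$simulate$n_days - 1
  obs_day <- campaign_day(obs, day)
  d <- obs_day$obs
  cell <- m$cell_size %||% (max(diff(range(d$x)), diff(range(d$y))) / m$n_x)
  hours <- m$times_hours %||%
    seq(cfg$simulate$day_start, cfg$simulate$day_start + cfg$simulate$day_hours - 1)
  grid <- grid_spec(min(d$x), min(d$y), m$n_x, m$n_y, cell,
                    times = day * 86400 + hours * 3600)
  map <- predict_grid(obs_day, station, models[[m$method]] %||% models$ok,
                      method = m$method, grid = grid, n_max = m$n_max)
  export_map(map, csv = p$map,
             raster_dir = if (isTRUE(m$rasters)) file.path(cfg$output_dir, "rasters"))
  list(map = p$map)
}

#' Write fitted variogram models to YAML
#' @param models Named list of `variogram_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variogram_models <- function(models, path) {
  yaml::write_yaml(lapply(models, function(m) {
    list(family = m$family, sill = m$sill, nugget = m$nugget,
         range = m$range, K = m$K)
  }), path)
  invisible(path)
}

#' Read fitted variogram models from YAML
#' @param path Input path.
#' @return Named list of `variogram_model`.
#' @export
read_variogram_models <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) {
    variogram_model(m$family, m$sill, m$nugget, m$range, m$K)
  })
}

#' Write an empirical variogram surface to CSV
#'
#' Long format: one row per bin with edges, gamma and pair count.
#'
#' @param emp An `empirical_variogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_empirical_variogram <- function(emp, path) {
  nsb <- nrow(emp$gamma); ntb <- ncol(emp$gamma)
  out <- data.frame(
    s_lo = rep(emp$s_edges[-(nsb + 1)], ntb),
    s_hi = rep(emp$s_edges[-1], ntb),
    u_lo = rep(emp$u_edges[-(ntb + 1)], each = nsb),
    u_hi = rep(emp$u_edges[-1], each = nsb),
    gamma = as.vector(emp$gamma),
    count = as.vector(emp$counts))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
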