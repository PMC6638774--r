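# Experiment configuration, validation, dispatch and serialisation. All
# randomness flows from a single master seed through named sub-streams; a
# content hash of the configuration is embedded in every output manifest.

.default_config <- function() {
  list(
    sky = list(d_max = 0.75, latitude = 37.3925, longitude = -5.8839,
               tz = 2, date = "2018-09-15"),
    sensor = list(n = 60, omega = 56, rho = 5.4),
    compass = list(n_sol = 8, n_tcl = 8, gating = TRUE, theta_g = 40,
                   sigma_g = 13, time_comp = FALSE),
    protocol = "evaluate",
    n_sun = 500,
    eta = 0,
    seed = 1
  )
}

#' Build an experiment configuration
#'
#' Merges user settings over the package defaults and validates them. The
#' configuration is a plain serialisable list (degrees everywhere) and can
#' be read from a YAML or JSON file.
#'
#' @param ... named overrides of the default configuration (nested lists
#'   `sky`, `sensor`, `compass` are merged field-wise).
#' @param file optional path to a YAML or JSON config file; `...` overrides
#'   the file.
#' @return a validated config list of class `experiment_config`, with a
#'   `hash` attribute.
#' @export
experiment_config <- function(..., file = NULL) {
  cfg <- .default_config()
  merge_in <- function(cfg, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(cfg[[nm]]))
        cfg[[nm]] <- merge_in(cfg[[nm]], upd[[nm]])
      else cfg[[nm]] <- upd[[nm]]
    }
    cfg
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    upd <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(file)
           else jsonlite::read_json(file, simplifyVector = TRUE)
    cfg <- merge_in(cfg, upd)
  }
  cfg <- merge_in(cfg, list(...))
  validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

#' Validate an experiment configuration
#'
#' @param cfg a configuration list.
#' @return `TRUE` invisibly; stops with an error naming the offending field
#'   otherwise.
#' @export
validate_config <- function(cfg) {
  check <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid config field '%s': %s", field, why),
                  call. = FALSE)
  }
  check(is.numeric(cfg$sky$d_max) && cfg$sky$d_max > 0 &&
          cfg$sky$d_max <= 1, "sky.d_max", "must be in (0, 1]")
  check(abs(cfg$sky$latitude) <= 90, "sky.latitude", "must be in [-90, 90]")
  check(cfg$sensor$n >= 1, "sensor.n", "must be >= 1")
  check(cfg$sensor$omega > 0 && cfg$sensor$omega <= 180, "sensor.omega",
        "must be in (0, 180]")
  check(cfg$compass$n_sol >= 4, "compass.n_sol", "must be >= 4")
  check(cfg$compass$n_tcl >= 4, "compass.n_tcl", "must be >= 4")
  check(cfg$compass$sigma_g > 0, "compass.sigma_g", "must be > 0")
  check(cfg$eta >= 0 && cfg$eta <= 1, "eta", "must be in [0, 1]")
  check(cfg$protocol %in% c("evaluate", "disturbance", "sweep-gating",
                            "sweep-layout", "sweep-populations", "behave",
                            "neurophys", "skymap"),
        "protocol", "unknown protocol")
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
        "must be a single number")
  invisible(TRUE)
}

#' Deterministic content hash of a configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON serialisation; embedded in
#' output manifests so results can be traced to their configuration.
#'
#' @param cfg a configuration list.
#' @return hexadecimal hash string.
#' @export
config_hash <- function(cfg) {
  attributes(cfg) <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- str_hash32(as.character(js))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run a configured experiment
#'
#' Executes the protocol named in the configuration and writes its outputs
#' (CSV tables plus a JSON summary and manifest) into `out_dir`.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing and just return results.
#' @return the protocol result, invisibly when written.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  array <- build_dra(cfg$sensor$n, cfg$sensor$omega, cfg$sensor$rho)
  compass <- build_compass(cfg$compass$n_sol, cfg$compass$n_tcl,
                           cfg$compass$gating, cfg$compass$theta_g,
                           cfg$compass$sigma_g, cfg$compass$time_comp)
  d_max <- cfg$sky$d_max
  res <- switch(
    cfg$protocol,
    evaluate = run_objective(compass, array,
                             eval_protocol(n_sun = cfg$n_sun,
                                           eta = cfg$eta,
                                           seed = cfg$seed),
                             d_max = d_max),
    disturbance = disturbance_curve(compass, array, seed = cfg$seed,
                                    d_max = d_max),
    `sweep-gating` = sweep_gating(array,
                                  protocol = eval_protocol(
                                    n_sun = cfg$n_sun, seed = cfg$seed),
                                  d_max = d_max),
    `sweep-layout` = sweep_layout(protocol = eval_protocol(
      n_sun = cfg$n_sun, seed = cfg$seed), d_max = d_max),
    `sweep-populations` = sweep_populations(
      array = array, protocol = eval_protocol(n_sun = cfg$n_sun,
                                              seed = cfg$seed),
      d_max = d_max),
    behave = {
      sky_cfg <- sky_config(d_max, cfg$sky$latitude, cfg$sky$longitude,
                            cfg$sky$tz, cfg$sky$date)
      terr <- generate_terrain(seed = derive_seed(cfg$seed, "terrain"))
      route <- generate_route(seed = derive_seed(cfg$seed, "route"))
      run_trial(route, terr, compass, array, eta = cfg$eta,
                time_comp = cfg$compass$time_comp, sky_cfg = sky_cfg,
                seed = cfg$seed)
    },
    neurophys = list(
      polariser = rotating_polariser_experiment(compass, array,
                                                n_trials = 10,
                                                eta = max(cfg$eta, 0.5),
                                                seed = cfg$seed),
      sky = rotating_sky_experiment(compass, array, n_trials = 100,
                                    eta = max(cfg$eta, 0.5),
                                    seed = cfg$seed, d_max = d_max)),
    skymap = {
      sun <- sun_position(30, 180)
      skydome_raster(sky_state(sun, sky_config(d_max)))
    })
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(res, cfg, out_dir)
  invisible(res)
}

# serialise a protocol result to CSV/JSON files plus a manifest
write_results <- function(res, cfg, out_dir) {
  pfx <- file.path(out_dir, cfg$protocol)
  summary <- list(protocol = cfg$protocol, seed = cfg$seed,
                  config_hash = attr(cfg, "hash"),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (inherits(res, "eval_result")) {
    if (!is.null(res$records))
      utils::write.csv(res$records, paste0(pfx, "_records.csv"),
                       row.names = FALSE)
    utils::write.csv(res$by_delta, paste0(pfx, "_by_delta.csv"),
                     row.names = FALSE)
    summary <- c(summary, list(J = res$J, se = res$se,
                               tau_mean = res$tau_mean, n = res$n))
  } else if (is.data.frame(res)) {
    utils::write.csv(res, paste0(pfx, ".csv"), row.names = FALSE)
  } else if (inherits(res, "trial_result")) {
    utils::write.csv(res$trajectory, paste0(pfx, "_trajectory.csv"),
                     row.names = FALSE)
    summary <- c(summary, list(endpoint_error = res$endpoint_error,
                               arrived = res$arrived,
                               tortuosity = res$metrics$final))
  } else if (is.list(res) && !is.null(res$grid)) {
    utils::write.csv(res$grid, paste0(pfx, "_grid.csv"), row.names = FALSE)
    summary <- c(summary, list(argmin = as.list(res$argmin)))
  } else if (is.list(res) && inherits(res$polariser, "tuning_set")) {
    utils::write.csv(rbind(tuning_table(res$polariser),
                           tuning_table(res$sky)),
                     paste0(pfx, "_curves.csv"), row.names = FALSE)
  }
  jsonlite::write_json(summary, paste0(pfx, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(list(config = unclass(cfg)), summary),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
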