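experiment_names <- c("fig1", "fig3", "fig4", "fig5", "fig6", "fig7", "custom")

default_run_config <- function() {
  list(
    experiment = "custom",
    seed = 1L,
    out_dir = NULL,
    mc = list(n = 12, t = 5000, k1 = 0.3, burn_in = 0),
    abm = list(n = 12, t = 1000, dt = 0.05, agent_radius = 1,
               arena_radius = 6.5, v1 = 1, v2 = 5, sigma = 0.01,
               n_sensors = 72, contact_slack = 0.05, overlap_tol = 0.5, k1 = 1),
    evolution = list(generations = 10000, per_gen_iterations = 1000,
                     alpha_mc = 6.06, alpha_abm = 3.0,
                     g_lo = 0, g_hi = 5, k2_lo = 0, k2_hi = 5),
    sweep = list(ta_min = 0, ta_max = 50, ta_step = 2, replicates = 20,
                 ta_evolution = c(0, 10, 20, 30, 40, 50)),
    criticality = list(n_bins = 30, g_lo = 0, g_hi = 5, threshold = 0.5,
                       r2_min = 0.8),
    t_a = 10, t_p = 37
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(paste0("unknown config key: `", full, "`"))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(paste0("config key `", full, "` must be a mapping"))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[key] <- list(user[[key]]) # keeps explicit NULLs
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (!cfg$experiment %in% experiment_names) {
    abort(paste0("unknown experiment `", cfg$experiment, "`; expected one of ",
                 paste(experiment_names, collapse = ", ")))
  }
  if (cfg$mc$k1 <= 0 || cfg$abm$k1 <= 0) abort("config key `k1` must be positive.")
  if (cfg$evolution$alpha_mc < 0 || cfg$evolution$alpha_abm < 0) {
    abort("config key `alpha` must be non-negative.")
  }
  if (cfg$sweep$ta_step <= 0) abort("config key `sweep.ta_step` must be positive.")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills every unset key with its default, and
#' rejects unknown keys. An empty file yields the all-defaults configuration
#' for a custom experiment. The configuration plus its seed determines every
#' output of [run_experiment()] exactly.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  cfg <- validate_run_config(merge_config(default_run_config(), user))
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly. `load_config(save_config(cfg, p))` round-trips.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

evolution_config_from <- function(cfg, model, t_a) {
  ev <- cfg$evolution
  if (model == "monte_carlo") {
    th <- thermo_params(t_a = t_a, t_p = cfg$t_p, k1 = cfg$mc$k1,
                        alpha = ev$alpha_mc)
    evolution_config("monte_carlo", generations = ev$generations,
                     per_gen_iterations = ev$per_gen_iterations, thermo = th,
                     n = cfg$mc$n, g_range = c(ev$g_lo, ev$g_hi),
                     k2_range = c(ev$k2_lo, ev$k2_hi))
  } else {
    th <- thermo_params(t_a = t_a, t_p = cfg$t_p, k1 = cfg$abm$k1,
                        alpha = ev$alpha_abm)
    a <- cfg$abm
    abm <- abm_config(n = a$n, t = ev$per_gen_iterations, dt = a$dt,
                      agent_radius = a$agent_radius,
                      arena_radius = a$arena_radius, v1 = a$v1, v2 = a$v2,
                      sigma = a$sigma, n_sensors = a$n_sensors,
                      contact_slack = a$contact_slack, overlap_tol = a$overlap_tol, thermo = th)
    evolution_config("agent_based", generations = ev$generations,
                     per_gen_iterations = ev$per_gen_iterations, thermo = th,
                     n = a$n, g_range = c(ev$g_lo, ev$g_hi),
                     k2_range = c(ev$k2_lo, ev$k2_hi), abm = abm)
  }
}

#' Run a named experiment
#'
#' Dispatches on `cfg$experiment`:
#' * `fig1`: Monte Carlo temperature sweep (one simulation per temperature).
#' * `fig3`/`fig6`: single evolutionary run (Monte Carlo / agent-based) at
#'   `t_a`, with avalanche segmentation and the power-law fit.
#' * `fig4`/`fig7`: evolutionary runs across `sweep$ta_evolution` with one
#'   power-law fit per temperature.
#' * `fig5`: agent-based temperature sweep with replicates.
#' * `custom`: the Monte Carlo sweep under the custom settings.
#'
#' When `cfg$out_dir` is set, tables are written as CSV with a JSON sidecar
#' recording the full configuration, seed and package version; rerunning the
#' same configuration reproduces the files byte-for-byte.
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A tibble of results (long format, one row per parameter
#'   combination), invisibly accompanied by files when `out_dir` is set.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cfg <- validate_run_config(cfg)
  withr::local_seed(cfg$seed)
  sw <- cfg$sweep
  ta_grid <- seq(sw$ta_min, sw$ta_max, by = sw$ta_step)
  res <- switch(cfg$experiment,
    fig1 = ,
    custom = {
      th <- thermo_params(t_a = cfg$t_a, t_p = cfg$t_p, k1 = cfg$mc$k1)
      mcc <- mc_config(n = cfg$mc$n, t = cfg$mc$t, thermo = th,
                       burn_in = cfg$mc$burn_in)
      mc_temperature_sweep(mcc, ta_grid,
                           g_range = c(cfg$evolution$g_lo, cfg$evolution$g_hi))
    },
    fig5 = {
      a <- cfg$abm
      th <- thermo_params(t_a = cfg$t_a, t_p = cfg$t_p, k1 = a$k1,
                          alpha = cfg$evolution$alpha_abm)
      ac <- abm_config(n = a$n, t = a$t, dt = a$dt,
                       agent_radius = a$agent_radius,
                       arena_radius = a$arena_radius, v1 = a$v1, v2 = a$v2,
                       sigma = a$sigma, n_sensors = a$n_sensors,
                       contact_slack = a$contact_slack, overlap_tol = a$overlap_tol, thermo = th)
      abm_temperature_sweep(ac, ta_grid, replicates = sw$replicates,
                            g_range = c(cfg$evolution$g_lo, cfg$evolution$g_hi),
                            k2_range = c(cfg$evolution$k2_lo, cfg$evolution$k2_hi))
    },
    fig3 = ,
    fig6 = {
      model <- if (cfg$experiment == "fig3") "monte_carlo" else "agent_based"
      tr <- evolve(evolution_config_from(cfg, model, cfg$t_a))
      dplyr::select(tr, -dplyr::any_of(c("f", "g", "k2")))
    },
    fig4 = ,
    fig7 = {
      model <- if (cfg$experiment == "fig4") "monte_carlo" else "agent_based"
      purrr::map_dfr(sw$ta_evolution, function(ta) {
        tr <- evolve(evolution_config_from(cfg, model, ta))
        tibble(t_a = ta, generation = tr$generation, g_min = tr$g_min,
               g_weakest = tr$g_weakest, f_weakest = tr$f_weakest,
               f_mean = tr$f_mean)
      })
    }
  )
  res <- dplyr::mutate(res, experiment = cfg$experiment, .before = 1)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(cfg$out_dir,
                                    paste0(cfg$experiment, ".csv")),
                     row.names = FALSE)
    sidecar <- list(
      config = unclass(cfg),
      package_version = as.character(utils::packageVersion("huddlesoc"))
    )
    if (cfg$experiment %in% c("fig4", "fig7")) {
      sidecar$exponents <- exponent_sweep(
        res, n_bins = cfg$criticality$n_bins,
        range = c(cfg$criticality$g_lo, cfg$criticality$g_hi),
        r2_min = cfg$criticality$r2_min)
    }
    jsonlite::write_json(sidecar,
                         file.path(cfg$out_dir,
                                   paste0(cfg$experiment, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
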