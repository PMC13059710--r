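#' Configuration for an end-to-end pipeline run
#'
#' A validated bag of run parameters. Unknown override keys are rejected so
#' that typos cannot silently fall back to defaults.
#'
#' @param seed Integer seed governing every random draw of the run.
#' @param module `"motor"`, `"fret"`, or `"rings"`.
#' @param preset Condition preset: a [preset_switching_model()] name for
#'   the motor module, a [preset_colony_z()] name for rings; ignored for
#'   fret.
#' @param out_dir Output directory.
#' @param n_units Number of motors / cells / observations to simulate.
#' @param overrides Named list of model-parameter overrides; allowed names
#'   are the formals of the relevant model constructors plus `duration_s`,
#'   `fps`, `stimulus_time_s`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, module = c("motor", "fret", "rings"),
                       preset = "wt_baseline", out_dir = tempfile("chemosignal_"),
                       n_units = 6L, overrides = list()) {
  module <- match.arg(module)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  allowed <- c("duration_s", "fps", "stimulus_time_s", "speed_hz",
               "orbit_radius_um", "position_noise_sd_um",
               "shot_noise_sd", "dt_s", "z_max_um", "noise_sd_px")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad) > 0L)
    stop("unknown override key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), module = module, preset = preset,
                 out_dir = out_dir, n_units = as.integer(n_units),
                 overrides = overrides),
            class = "run_config")
}

#' Run a simulate-then-analyze pipeline
#'
#' Simulates the configured number of units from the preset forward model,
#' writes the traces plus ground-truth sidecars, runs the matching analysis
#' module, and writes a JSON summary (all numeric keys carry units in
#' their names) together with a resolved copy of the configuration. Output
#' is deterministic for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (the summary list) and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ov <- config$overrides
  summary <- switch(config$module,
                    motor = run_motor_pipeline(config, ov),
                    fret = run_fret_pipeline(config, ov),
                    rings = run_rings_pipeline(config, ov))
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  config_path <- file.path(config$out_dir, "resolved_config.json")
  jsonlite::write_json(unclass(config), config_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(summary = summary,
                 paths = list(summary = summary_path, config = config_path)))
}

run_motor_pipeline <- function(config, ov) {
  t_stim <- ov$stimulus_time_s %||% 60
  model <- preset_switching_model(config$preset, stimulus_time_s = t_stim,
                                  speed_hz = ov$speed_hz %||% 25)
  duration <- ov$duration_s %||% attr(model, "recommended_duration_s")
  fps <- ov$fps %||% 250
  pre_sum <- vector("list", config$n_units)
  post_sum <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    sim <- simulate_motor_trace(
      model, duration_s = duration, fps = fps,
      orbit_radius_um = ov$orbit_radius_um %||% 0.25,
      position_noise_sd_um = ov$position_noise_sd_um %||% 0.02,
      seed = config$seed + i)
    write_motor_simulation(sim, config$out_dir,
                           basename = sprintf("motor_%02d", i), model = model)
    rot <- estimate_rotation(sim$trace)
    ds <- classify_direction(rot)
    pre_sum[[i]] <- summarize_motor(ds, window = c(0, t_stim))
    post_sum[[i]] <- summarize_motor(ds, window = c(t_stim, duration))
  }
  cmp <- if (config$n_units >= 2L) {
    compare_pre_post(pre_sum, post_sum)
  } else NULL
  mean_of <- function(lst, f) mean(vapply(lst, function(s) s[[f]], numeric(1)))
  truth_stats <- list(
    stationary_cw_bias = stationary_cw_bias(model),
    baseline_reversals_per_min = 2 * model$rate_ccw_to_cw * model$rate_cw_to_ccw /
      (model$rate_ccw_to_cw + model$rate_cw_to_ccw) * 60)
  list(module = "motor", preset = config$preset, n_motors = config$n_units,
       stimulus_time_s = t_stim, duration_s = duration, fps = fps,
       pre = list(cw_bias = mean_of(pre_sum, "cw_bias"),
                  reversal_rate_per_min = mean_of(pre_sum, "reversal_rate_per_min"),
                  mean_speed_hz = mean_of(pre_sum, "mean_speed_hz")),
       post = list(cw_bias = mean_of(post_sum, "cw_bias"),
                   reversal_rate_per_min = mean_of(post_sum, "reversal_rate_per_min"),
                   mean_speed_hz = mean_of(post_sum, "mean_speed_hz")),
       pre_vs_post = if (!is.null(cmp)) cmp[c("statistic", "df", "p_value",
                                              "metric", "method")] else NULL,
       generator_truth = truth_stats)
}

run_fret_pipeline <- function(config, ov) {
  constants <- efret_constants()
  schedule <- default_fret_schedule(ov$duration_s %||% 600)
  res <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    exp <- simulate_fret_experiment(
      schedule = schedule, constants = constants,
      dt_s = ov$dt_s %||% 0.05,
      shot_noise_sd = ov$shot_noise_sd %||% 0.01,
      seed = config$seed + i, cell_id = sprintf("cell_%02d", i))
    write_fret_trace(exp, file.path(config$out_dir,
                                    sprintf("fret_cell_%02d.csv", i)))
    res[[i]] <- analyze_fret_experiment(exp, constants)
  }
  adapt <- vapply(res, function(r) r$summary$adaptation_time_s, numeric(1))
  base <- vapply(res, function(r) r$summary$baseline, numeric(1))
  peak <- vapply(res, function(r) r$summary$peak_activity, numeric(1))
  list(module = "fret", n_cells = config$n_units,
       baseline_activity_mean = mean(base),
       peak_activity_mean = mean(peak),
       adaptation_time_s_mean = mean(adapt, na.rm = TRUE),
       n_no_response = sum(is.na(adapt)))
}

run_rings_pipeline <- function(config, ov) {
  calib <- ring_calibration(z_max_um = ov$z_max_um %||% 150,
                            noise_sd_px = ov$noise_sd_px %||% 0.1)
  n_rep <- 3L
  obs <- do.call(rbind, lapply(seq_len(n_rep), function(rep) {
    rbind(
      simulate_ring_observations(
        calib, preset_colony_z(config$preset %||% "wt_kanamycin",
                               config$n_units, seed = config$seed + rep),
        seed = config$seed + 100L + rep,
        condition = config$preset, replicate = rep),
      simulate_ring_observations(
        calib, preset_colony_z("aer_null", config$n_units,
                               seed = config$seed + 200L + rep),
        seed = config$seed + 300L + rep,
        condition = "aer_null", replicate = rep))
  }))
  obs$z_um <- as.numeric(diameter_to_z(obs$diameter_px, calib))
  write_ring_observations(obs, file.path(config$out_dir, "rings.csv"))
  cs <- summarize_colony(obs, control = "aer_null")
  list(module = "rings", per_condition = cs$per_condition, tests = cs$tests)
}
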