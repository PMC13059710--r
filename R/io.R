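# File formats: comma-separated, UTF-8, '.' decimal, mandatory header.
# Numeric columns are written with 17 significant digits so a write/read
# round trip is lossless for finite doubles.

write_csv_lossless <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- do.call(cbind, fmt)
  colnames(out) <- names(df)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

validate_time_column <- function(t, path) {
  if (anyNA(t)) {
    i <- which(is.na(t))[1L]
    stop(sprintf("schema error in '%s': NaN/NA time at row %d", path, i),
         call. = FALSE)
  }
  d <- diff(t)
  if (any(d == 0)) {
    i <- which(d == 0)[1L]
    stop(sprintf("schema error in '%s': duplicated timestamp at row %d",
                 path, i + 1L), call. = FALSE)
  }
  if (any(d < 0)) {
    i <- which(d < 0)[1L]
    stop(sprintf("schema error in '%s': non-monotonic time at row %d",
                 path, i + 1L), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write bead-assay motor traces
#'
#' Motor traces are CSV files with header `time_s,x_um,y_um` (positions) or
#' `time_s,angle_rad` (pre-extracted angles). Time must be strictly
#' increasing and uniform; the frame rate is inferred and attached.
#'
#' @param path CSV file path.
#' @return For `read_motor_trace`, a `motor_trace` data frame with
#'   attribute `fps`; angle-only files carry `theta_rad` instead of
#'   positions.
#' @export
read_motor_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("angle_rad" %in% names(df)) {
    require_columns(df, c("time_s", "angle_rad"), path)
  } else {
    require_columns(df, c("time_s", "x_um", "y_um"), path)
  }
  validate_time_column(df$time_s, path)
  check_uniform_time(df$time_s, what = sprintf("'%s' time", path))
  class(df) <- c("motor_trace", "data.frame")
  attr(df, "fps") <- infer_fps(df$time_s)
  df
}

#' @param trace A `motor_trace` data frame.
#' @rdname read_motor_trace
#' @export
write_motor_trace <- function(trace, path) {
  cols <- intersect(c("time_s", "x_um", "y_um", "angle_rad"), names(trace))
  write_csv_lossless(as.data.frame(trace)[, cols, drop = FALSE], path)
}

#' Read / write three-channel FRET traces
#'
#' Per-cell CSV files with header `time_s,IDD,IDA,IAA` (counts).
#'
#' @param path CSV file path.
#' @return For `read_fret_trace`, a `fret_experiment` data frame.
#' @export
read_fret_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("time_s", "IDD", "IDA", "IAA"), path)
  validate_time_column(df$time_s, path)
  check_uniform_time(df$time_s, what = sprintf("'%s' time", path))
  if (any(df$IDD < 0 | df$IDA < 0 | df$IAA < 0, na.rm = TRUE))
    stop(sprintf("schema error in '%s': negative intensities", path), call. = FALSE)
  class(df) <- c("fret_experiment", "data.frame")
  df
}

#' @param exp A `fret_experiment` data frame.
#' @rdname read_fret_trace
#' @export
write_fret_trace <- function(exp, path) {
  write_csv_lossless(as.data.frame(exp)[, c("time_s", "IDD", "IDA", "IAA")], path)
}

#' Read / write ring observations
#'
#' CSV files with header `x_um,diameter_px,condition,replicate` (or `z_um`
#' in place of / in addition to `diameter_px`).
#'
#' @param path CSV file path.
#' @return For `read_ring_observations`, a `ring_observations` data frame.
#' @export
read_ring_observations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("diameter_px" %in% names(df) || "z_um" %in% names(df)))
    stop(sprintf("schema error in '%s': need a diameter_px or z_um column", path),
         call. = FALSE)
  require_columns(df, c("condition", "replicate"), path)
  if ("diameter_px" %in% names(df) && any(df$diameter_px < 0, na.rm = TRUE))
    stop(sprintf("schema error in '%s': negative ring diameters", path),
         call. = FALSE)
  class(df) <- c("ring_observations", "data.frame")
  df
}

#' @param observations A `ring_observations` data frame.
#' @rdname read_ring_observations
#' @export
write_ring_observations <- function(observations, path) {
  write_csv_lossless(as.data.frame(observations), path)
}

#' Read a ring calibration from YAML
#'
#' Expected keys: `d0_px`, `slope_px_per_um`, `z_max_um`, optional
#' `noise_sd_px`.
#'
#' @param path YAML file path.
#' @return A [ring_calibration()].
#' @export
read_calibration_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ring_calibration(d0_px = y$d0_px, slope_px_per_um = y$slope_px_per_um,
                   z_max_um = y$z_max_um %||% 150,
                   noise_sd_px = y$noise_sd_px %||% 0.1)
}

#' Read a stimulus schedule from YAML
#'
#' Expected structure: `duration_s`, a list `events` of `{time_s, kind,
#' ligand, concentration}` maps, and a list `saturating_windows` of
#' `{t_start, t_end, extreme}` maps.
#'
#' @param path YAML file path.
#' @return A [stimulus_schedule()].
#' @export
read_schedule_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(lst) if (is.null(lst)) NULL else
    do.call(rbind, lapply(lst, function(e) as.data.frame(e, stringsAsFactors = FALSE)))
  stimulus_schedule(events = to_df(y$events),
                    saturating_windows = to_df(y$saturating_windows),
                    duration_s = y$duration_s)
}

#' Write a simulated motor recording with its ground truth
#'
#' Writes the trace CSV, a ground-truth direction CSV, and a JSON sidecar
#' holding the generator parameters and summary statistics of the exact
#' switch path.
#'
#' @param sim Result of [simulate_motor_trace()].
#' @param dir Output directory (created if absent).
#' @param basename File stem; default `"motor"`.
#' @param model The generating [switching_model()] (stored in the sidecar).
#' @return Invisibly, the sidecar path.
#' @export
write_motor_simulation <- function(sim, dir, basename = "motor", model = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trace_path <- file.path(dir, paste0(basename, "_trace.csv"))
  truth_path <- file.path(dir, paste0(basename, "_truth.csv"))
  write_motor_trace(sim$trace, trace_path)
  write_csv_lossless(as.data.frame(sim$truth), truth_path)
  fps <- attr(sim$trace, "fps")
  sidecar <- list(
    files = list(trace = basename(trace_path), truth = basename(truth_path)),
    parameters = if (!is.null(model)) unclass(model)[c(
      "rate_ccw_to_cw", "rate_cw_to_ccw", "speed_hz",
      "pause_prob_per_switch", "adapt_tau_s")] else NULL,
    ground_truth = list(
      n_reversals = attr(sim$truth, "n_reversals"),
      duration_s = nrow(sim$trace) / fps,
      fps = fps))
  side_path <- file.path(dir, paste0(basename, "_sidecar.json"))
  jsonlite::write_json(sidecar, side_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side_path)
}
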