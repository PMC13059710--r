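#' Estimate bead rotation angle and signed speed from a trajectory
#'
#' Converts bead x/y positions into an unwrapped rotation angle and a signed
#' rotation speed. The orbit center is a running centroid of the positions
#' (beads drift slowly relative to their ~tens-of-Hz rotation), the angle is
#' `atan2` about that center, unwrapped, and the angular velocity comes from
#' a central difference. The assay's sign convention is applied at the end:
#' CW rotation is positive, CCW negative, so a bead whose mathematical angle
#' increases (CCW in standard axes) gets a negative signed speed.
#'
#' @param trace A `motor_trace` data frame with columns `time_s`, `x_um`,
#'   `y_um` (e.g. from [simulate_motor_trace()] or [read_motor_trace()]).
#' @param center_window_s Length of the running-centroid window (s).
#' @param velocity_smooth_s Optional centered running-mean window applied to
#'   the angular velocity (s); 0 disables smoothing (default).
#' @param image_y_down Set `TRUE` when the trajectory is in screen
#'   coordinates with the y axis pointing down, which flips the apparent
#'   chirality.
#' @return A data frame with columns `time_s`, `theta_rad` (unwrapped),
#'   `signed_speed_hz`, and attributes `fps`, `orbit_radius_um`,
#'   `radius_snr`.
#' @export
estimate_rotation <- function(trace, center_window_s = 1,
                              velocity_smooth_s = 0, image_y_down = FALSE) {
  stopifnot(all(c("time_s", "x_um", "y_um") %in% names(trace)))
  t <- trace$time_s
  n <- length(t)
  if (n < 10L) stop("need at least 10 frames to estimate rotation", call. = FALSE)
  fps <- attr(trace, "fps") %||% infer_fps(t)
  w <- max(1L, round(center_window_s * fps))
  cx <- rolling_mean(trace$x_um, w)
  cy <- rolling_mean(trace$y_um, w)
  dx <- trace$x_um - cx
  dy <- trace$y_um - cy
  if (image_y_down) dy <- -dy
  r <- sqrt(dx^2 + dy^2)
  radius <- stats::median(r)
  if (radius < .Machine$double.eps^0.5)
    stop("degenerate trace: zero orbit radius, cannot estimate rotation",
         call. = FALSE)
  noise_sd <- stats::mad(r - radius)
  snr <- if (noise_sd > 0) radius / noise_sd else Inf
  if (snr < 2)
    warning(sprintf("orbit radius (%.3g um) is close to the noise floor (SNR %.2f)",
                    radius, snr), call. = FALSE)
  theta <- unwrap_angle(atan2(dy, dx))
  # central difference; one-sided at the ends
  omega <- c(theta[2L] - theta[1L],
             (theta[3:n] - theta[1:(n - 2L)]) / 2,
             theta[n] - theta[n - 1L]) * fps
  if (velocity_smooth_s > 0)
    omega <- rolling_mean(omega, max(1L, round(velocity_smooth_s * fps)))
  out <- data.frame(time_s = t, theta_rad = theta,
                    signed_speed_hz = -omega / (2 * pi))
  attr(out, "fps") <- fps
  attr(out, "orbit_radius_um") <- radius
  attr(out, "radius_snr") <- snr
  out
}

#' Classify per-frame rotation direction
#'
#' Thresholds the signed rotation speed into CW / CCW / PAUSE labels and
#' debounces the label series: runs shorter than `min_dwell_s` are merged
#' into the flanking state so that localization noise cannot manufacture
#' spurious reversals.
#'
#' @param rotation Output of [estimate_rotation()] (or any data frame with
#'   `time_s` and `signed_speed_hz`).
#' @param pause_threshold_hz Speeds with absolute value below this are
#'   labelled PAUSE (Hz). Default 2.
#' @param min_dwell_s Minimum dwell: label runs shorter than this are merged
#'   into the preceding state (s). Default 0.01.
#' @return A `direction_series` data frame (`time_s`, `state`,
#'   `signed_speed_hz` with PAUSE frames set to 0), attribute `degenerate`
#'   flagging an all-pause output.
#' @export
classify_direction <- function(rotation, pause_threshold_hz = 2,
                               min_dwell_s = 0.01) {
  stopifnot(all(c("time_s", "signed_speed_hz") %in% names(rotation)))
  if (pause_threshold_hz < 0 || min_dwell_s < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  v <- rotation$signed_speed_hz
  fps <- attr(rotation, "fps") %||% infer_fps(rotation$time_s)
  state <- ifelse(v > pause_threshold_hz, "CW",
                  ifelse(v < -pause_threshold_hz, "CCW", "PAUSE"))
  min_frames <- max(1L, round(min_dwell_s * fps))
  if (min_frames > 1L) {
    for (pass in 1:10) {
      r <- rle(state)
      short <- which(r$lengths < min_frames)
      short <- setdiff(short, if (length(r$lengths) == 1L) 1L else integer(0))
      if (length(short) == 0L) break
      # merge each short run into its predecessor (first run into successor)
      for (i in short) r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
      state <- inverse.rle(r)
    }
  }
  out <- data.frame(time_s = rotation$time_s, state = state,
                    signed_speed_hz = ifelse(state == "PAUSE", 0, v),
                    stringsAsFactors = FALSE)
  class(out) <- c("direction_series", "data.frame")
  attr(out, "fps") <- fps
  attr(out, "degenerate") <- all(state == "PAUSE")
  if (attr(out, "degenerate"))
    warning("all frames classified as PAUSE", call. = FALSE)
  out
}

subset_window <- function(ds, window = NULL) {
  if (is.null(window)) return(ds)
  stopifnot(length(window) == 2L)
  ds[ds$time_s >= window[1L] & ds$time_s < window[2L], , drop = FALSE]
}

#' CW bias of a direction series
#'
#' CW bias is the fraction of time the motor rotates CW within an interval,
#' computed as the ratio of CW-labelled frames to all direction-labelled
#' frames in the interval. PAUSE frames enter neither numerator nor
#' denominator.
#'
#' @param ds A `direction_series`.
#' @param window Optional `c(t_start, t_end)` in seconds; default whole series.
#' @return CW bias, a fraction in \[0, 1\].
#' @export
compute_cw_bias <- function(ds, window = NULL) {
  d <- subset_window(ds, window)
  s <- d$state[d$state != "PAUSE"]
  if (length(s) == 0L)
    stop("undefined CW bias: window contains no CW or CCW frames", call. = FALSE)
  mean(s == "CW")
}

#' Running-average CW bias
#'
#' CW bias in a centered running window (default 30 s), the standard
#' smoothing used when displaying long motor recordings. Windows are
#' truncated at the recording edges.
#'
#' @param ds A `direction_series`.
#' @param window_s Running-window length (s). Default 30.
#' @return Data frame `time_s`, `cw_bias` (NA where the window holds no
#'   direction-labelled frame); attribute `whole_trace` is TRUE when the
#'   recording was shorter than the window and a single whole-trace value
#'   was returned.
#' @export
smooth_cw_bias <- function(ds, window_s = 30) {
  fps <- attr(ds, "fps") %||% infer_fps(ds$time_s)
  span <- length(ds$time_s) / fps
  if (span < window_s) {
    warning("recording shorter than the smoothing window; returning the whole-trace CW bias",
            call. = FALSE)
    out <- data.frame(time_s = stats::median(ds$time_s),
                      cw_bias = compute_cw_bias(ds))
    attr(out, "whole_trace") <- TRUE
    return(out)
  }
  cw <- ifelse(ds$state == "PAUSE", NA_real_, as.numeric(ds$state == "CW"))
  w <- max(1L, round(window_s * fps))
  rc <- rolling_sum_count(cw, w)
  bias <- ifelse(rc$count > 0L, rc$sum / rc$count, NA_real_)
  out <- data.frame(time_s = ds$time_s, cw_bias = bias)
  attr(out, "whole_trace") <- FALSE
  out
}

#' Reversal rate of a direction series
#'
#' A reversal is one CW/CCW direction change after debouncing. Transitions
#' bridged by pauses count once (CCW, PAUSE, CW is one reversal; CCW,
#' PAUSE, CCW is none). The rate is the transition count divided by the
#' window duration, in reversals per minute.
#'
#' @param ds A `direction_series`.
#' @param window Optional `c(t_start, t_end)` (s); default whole series.
#' @return Reversal rate (reversals/min) with attributes `n_reversals` and
#'   `duration_s`.
#' @export
count_reversals <- function(ds, window = NULL) {
  d <- subset_window(ds, window)
  fps <- attr(ds, "fps") %||% infer_fps(ds$time_s)
  duration <- if (is.null(window)) nrow(d) / fps else window[2L] - window[1L]
  if (duration < 1) stop("window must span at least 1 s", call. = FALSE)
  s <- d$state[d$state != "PAUSE"]
  n_rev <- if (length(s) < 2L) 0L else sum(s[-1L] != s[-length(s)])
  rate <- n_rev / duration * 60
  attr(rate, "n_reversals") <- n_rev
  attr(rate, "duration_s") <- duration
  rate
}

#' Summarize one motor over a time window
#'
#' @param ds A `direction_series`.
#' @param window Optional `c(t_start, t_end)` (s).
#' @return A `motor_summary` list: `cw_bias`, `reversal_rate_per_min`,
#'   `mean_speed_hz` (mean absolute speed over direction-labelled frames),
#'   `window`, and frame counts `n_frames_cw`, `n_frames_ccw`,
#'   `n_frames_pause`.
#' @export
summarize_motor <- function(ds, window = NULL) {
  d <- subset_window(ds, window)
  fps <- attr(ds, "fps") %||% infer_fps(ds$time_s)
  win <- window %||% c(d$time_s[1L], d$time_s[nrow(d)] + 1 / fps)
  moving <- d$state != "PAUSE"
  out <- list(cw_bias = compute_cw_bias(ds, window),
              reversal_rate_per_min = as.numeric(count_reversals(ds, window)),
              mean_speed_hz = mean(abs(d$signed_speed_hz[moving])),
              window = win,
              n_frames_cw = sum(d$state == "CW"),
              n_frames_ccw = sum(d$state == "CCW"),
              n_frames_pause = sum(d$state == "PAUSE"))
  class(out) <- "motor_summary"
  out
}

#' @export
print.motor_summary <- function(x, ...) {
  cat(sprintf("Motor summary over [%.1f, %.1f] s\n", x$window[1L], x$window[2L]))
  cat(sprintf("  CW bias        : %.3f\n", x$cw_bias))
  cat(sprintf("  reversal rate  : %.2f /min\n", x$reversal_rate_per_min))
  cat(sprintf("  mean speed     : %.2f Hz\n", x$mean_speed_hz))
  invisible(x)
}

#' Compare a motor statistic between two groups of motors
#'
#' Two-sample Student's t-test (equal variance by default, Welch optional)
#' on a per-motor summary statistic, e.g. pre- versus post-stimulus reversal
#' rates across motors.
#'
#' @param pre,post Numeric vectors, or lists of [summarize_motor()] results
#'   from which `metric` is extracted.
#' @param metric Name of the summary element to compare when summaries are
#'   given. Default `"reversal_rate_per_min"`.
#' @param var_equal Use the classical equal-variance Student's t (default
#'   TRUE); FALSE gives Welch's t.
#' @return List with `statistic` (t), `df`, `p_value`, group means and
#'   standard errors, `metric` and `method`.
#' @export
compare_pre_post <- function(pre, post, metric = "reversal_rate_per_min",
                             var_equal = TRUE) {
  pull <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(s) as.numeric(s[[metric]]), numeric(1))
  }
  x <- pull(pre); y <- pull(post)
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient replicates: need at least 2 motors per group", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = var_equal)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_pre = mean(x), sem_pre = sem(x),
       mean_post = mean(y), sem_post = sem(y),
       n_pre = length(x), n_post = length(y),
       metric = metric,
       method = tt$method)
}
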