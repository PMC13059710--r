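#' Sample the exact jump path of a switching model
#'
#' Draws the continuous-time state path of the two-state motor model by
#' exact exponential dwell sampling. Time-varying rates inside stimulus
#' windows are handled by thinning against the per-state rate envelope,
#' which leaves the sampled path exact. Pauses, when enabled, are inserted
#' at switch events with a fixed dwell.
#'
#' @param model A [switching_model()].
#' @param duration_s Path duration (s), > 0.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param init_state Initial state, `"CCW"` or `"CW"`; default samples from
#'   the stationary distribution of the baseline rates. Required when both
#'   rates are zero.
#' @return A data frame with columns `t_start`, `t_end`, `state`
#'   (`"CCW"`, `"CW"` or `"PAUSE"`), carrying attribute `n_reversals`
#'   (number of CW/CCW direction changes, pause-bridged changes counted
#'   once).
#' @export
simulate_switch_path <- function(model, duration_s, seed = NULL, init_state = NULL) {
  stopifnot(inherits(model, "switching_model"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  both_zero <- model$rate_ccw_to_cw == 0 && model$rate_cw_to_ccw == 0 &&
    is.null(model$stimulus_rate_map)
  if (both_zero && is.null(init_state))
    stop("both switching rates are zero: an explicit init_state is required",
         call. = FALSE)
  with_local_seed(seed, {
    if (is.null(init_state)) {
      p_cw <- stationary_cw_bias(model)
      state <- if (stats::runif(1) < p_cw) "CW" else "CCW"
    } else {
      state <- match.arg(init_state, c("CCW", "CW"))
    }
    t <- 0
    t_start <- numeric(0)
    t_end <- numeric(0)
    states <- character(0)
    seg_open <- t
    repeat {
      bound <- switch_rate_bound(model, state)
      if (bound <= 0) {                     # absorbing state
        t <- duration_s
        break
      }
      dt <- stats::rexp(1, bound)
      t_next <- t + dt
      if (t_next >= duration_s) {
        t <- duration_s
        break
      }
      accept <- stats::runif(1) <= switch_rate_at(model, state, t_next) / bound
      t <- t_next
      if (!accept) next
      # close current segment, optionally insert a pause, flip state
      t_start <- c(t_start, seg_open); t_end <- c(t_end, t); states <- c(states, state)
      seg_open <- t
      if (model$pause_prob_per_switch > 0 &&
          stats::runif(1) < model$pause_prob_per_switch) {
        p_end <- min(t + model$pause_dwell_s, duration_s)
        t_start <- c(t_start, seg_open); t_end <- c(t_end, p_end)
        states <- c(states, "PAUSE")
        seg_open <- p_end
        t <- p_end
        if (t >= duration_s) break
      }
      state <- if (state == "CCW") "CW" else "CCW"
    }
    if (seg_open < duration_s) {
      t_start <- c(t_start, seg_open); t_end <- c(t_end, duration_s)
      states <- c(states, state)
    }
    path <- data.frame(t_start = t_start, t_end = t_end, state = states,
                       stringsAsFactors = FALSE)
    dir_states <- path$state[path$state != "PAUSE"]
    attr(path, "n_reversals") <-
      if (length(dir_states) < 2L) 0L else sum(dir_states[-1L] != dir_states[-length(dir_states)])
    path
  })
}

#' Simulate a bead-assay motor recording
#'
#' Generates a synthetic bead trajectory from the two-state switching model:
#' the exact continuous-time state path is discretized at the frame rate,
#' the bead angle integrates +/- 2*pi*speed_hz per second according to the
#' rotation state (CCW increases the mathematical angle), and positions are
#' the orbit circle plus isotropic Gaussian localization noise.
#'
#' @param model A [switching_model()].
#' @param duration_s Recording duration (s), > 0.
#' @param fps Frame rate (frames/s), > 0.
#' @param orbit_radius_um Bead orbit radius (um). Default 0.25.
#' @param position_noise_sd_um Per-axis Gaussian localization noise SD (um).
#' @param seed Optional integer seed (reproducible output).
#' @param init_state Optional initial rotation state passed to
#'   [simulate_switch_path()].
#' @param center_um Orbit center, length-2 (um).
#' @return A list with elements:
#' \describe{
#'   \item{trace}{`motor_trace` data frame (`time_s`, `x_um`, `y_um`) with
#'     attributes `fps` and `metadata`.}
#'   \item{truth}{`direction_series` data frame (`time_s`, `state`,
#'     `signed_speed_hz`; CW positive, CCW negative per the assay's sign
#'     convention) with attributes `fps`, `n_reversals` and `switch_path`
#'     (the exact jump path).}
#' }
#' @export
simulate_motor_trace <- function(model, duration_s, fps = 250,
                                 orbit_radius_um = 0.25,
                                 position_noise_sd_um = 0.02,
                                 seed = NULL, init_state = NULL,
                                 center_um = c(0, 0)) {
  stopifnot(inherits(model, "switching_model"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0", call. = FALSE)
  with_local_seed(seed, {
    path <- simulate_switch_path(model, duration_s, seed = NULL,
                                 init_state = init_state)
    n <- floor(duration_s * fps)
    t <- (seq_len(n) - 1L) / fps
    # mathematical angle: CCW = +1, CW = -1, PAUSE = 0
    sgn <- c(CCW = 1, CW = -1, PAUSE = 0)[path$state]
    seg_len <- path$t_end - path$t_start
    ang0 <- c(0, cumsum(sgn * 2 * pi * model$speed_hz * seg_len))
    idx <- findInterval(t, path$t_start)
    theta <- ang0[idx] + sgn[idx] * 2 * pi * model$speed_hz * (t - path$t_start[idx])
    x <- center_um[1L] + orbit_radius_um * cos(theta) +
      stats::rnorm(n, 0, position_noise_sd_um)
    y <- center_um[2L] + orbit_radius_um * sin(theta) +
      stats::rnorm(n, 0, position_noise_sd_um)
    trace <- data.frame(time_s = t, x_um = x, y_um = y)
    class(trace) <- c("motor_trace", "data.frame")
    attr(trace, "fps") <- fps
    attr(trace, "metadata") <- list(orbit_radius_um = orbit_radius_um,
                                    position_noise_sd_um = position_noise_sd_um,
                                    preset = attr(model, "preset"))
    # ground truth uses the assay sign convention: CW positive, CCW negative
    speed <- c(CCW = -model$speed_hz, CW = model$speed_hz, PAUSE = 0)[path$state]
    truth <- data.frame(time_s = t,
                        state = path$state[idx],
                        signed_speed_hz = unname(speed[idx]),
                        stringsAsFactors = FALSE)
    class(truth) <- c("direction_series", "data.frame")
    attr(truth, "fps") <- fps
    attr(truth, "n_reversals") <- attr(path, "n_reversals")
    attr(truth, "switch_path") <- path
    list(trace = trace, truth = truth)
  })
}
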