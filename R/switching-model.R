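#' Two-state flagellar-motor switching model
#'
#' Minimal continuous-time Markov model of the bidirectional flagellar motor:
#' the motor alternates between CCW (the default "run" state) and CW
#' (the "tumble" state) with exponential dwell times. Stimuli are expressed
#' as time-windowed overrides of the two switching rates; within a window the
#' rates jump to the override values at the window start and relax back
#' toward baseline with a single-exponential adaptation time constant.
#'
#' @param rate_ccw_to_cw Baseline CCW-to-CW switching rate (events/s).
#' @param rate_cw_to_ccw Baseline CW-to-CCW switching rate (events/s).
#' @param speed_hz Rotation speed of the bead orbit (revolutions/s).
#' @param pause_prob_per_switch Probability that a switch is interrupted by a
#'   brief pause (fraction in \[0, 1\]; default 0, i.e. pauses off).
#' @param pause_dwell_s Fixed pause duration when a pause is inserted (s).
#' @param stimulus_rate_map Optional data frame with columns `t_start`,
#'   `t_end`, `rate_ccw_to_cw`, `rate_cw_to_ccw` giving non-overlapping
#'   time windows in which the switching rates are overridden.
#' @param adapt_tau_s Adaptation time constant (s) with which overridden
#'   rates relax back toward baseline inside a stimulus window; `Inf` holds
#'   the override constant for the whole window. Default 60 s.
#'
#' @return An object of class `switching_model`.
#' @seealso [simulate_motor_trace()], [stationary_cw_bias()],
#'   [preset_switching_model()]
#' @export
switching_model <- function(rate_ccw_to_cw, rate_cw_to_ccw, speed_hz = 50,
                            pause_prob_per_switch = 0, pause_dwell_s = 0.1,
                            stimulus_rate_map = NULL, adapt_tau_s = 60) {
  stopifnot(is.numeric(rate_ccw_to_cw), length(rate_ccw_to_cw) == 1L,
            is.numeric(rate_cw_to_ccw), length(rate_cw_to_ccw) == 1L)
  if (rate_ccw_to_cw < 0 || rate_cw_to_ccw < 0)
    stop("switching rates must be >= 0", call. = FALSE)
  if (!is.numeric(speed_hz) || speed_hz <= 0)
    stop("speed_hz must be > 0", call. = FALSE)
  if (pause_prob_per_switch < 0 || pause_prob_per_switch > 1)
    stop("pause_prob_per_switch must lie in [0, 1]", call. = FALSE)
  if (pause_dwell_s <= 0) stop("pause_dwell_s must be > 0", call. = FALSE)
  if (adapt_tau_s <= 0) stop("adapt_tau_s must be > 0", call. = FALSE)
  if (!is.null(stimulus_rate_map)) {
    m <- as.data.frame(stimulus_rate_map)
    need <- c("t_start", "t_end", "rate_ccw_to_cw", "rate_cw_to_ccw")
    if (!all(need %in% names(m)))
      stop("stimulus_rate_map needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(m$t_end <= m$t_start)) stop("stimulus windows must have t_end > t_start",
                                        call. = FALSE)
    if (any(m$rate_ccw_to_cw < 0) || any(m$rate_cw_to_ccw < 0))
      stop("override rates must be >= 0", call. = FALSE)
    m <- m[order(m$t_start), , drop = FALSE]
    if (nrow(m) > 1L && any(m$t_start[-1L] < m$t_end[-nrow(m)]))
      stop("stimulus windows must not overlap", call. = FALSE)
    stimulus_rate_map <- m
  }
  structure(list(rate_ccw_to_cw = rate_ccw_to_cw,
                 rate_cw_to_ccw = rate_cw_to_ccw,
                 speed_hz = speed_hz,
                 pause_prob_per_switch = pause_prob_per_switch,
                 pause_dwell_s = pause_dwell_s,
                 stimulus_rate_map = stimulus_rate_map,
                 adapt_tau_s = adapt_tau_s),
            class = "switching_model")
}

#' Stationary CW bias of a switching model
#'
#' For baseline rates a = CCW-to-CW and b = CW-to-CCW, the stationary
#' fraction of time spent CW is a / (a + b).
#'
#' @param model A [switching_model()].
#' @return CW bias as a fraction in \[0, 1\].
#' @export
stationary_cw_bias <- function(model) {
  a <- model$rate_ccw_to_cw
  b <- model$rate_cw_to_ccw
  if (a + b == 0) stop("both rates are zero; stationary bias undefined", call. = FALSE)
  a / (a + b)
}

# Instantaneous switching rate out of `from_state` at time t, honouring
# stimulus windows with exponential relaxation back to baseline.
switch_rate_at <- function(model, from_state, t) {
  base <- if (from_state == "CCW") model$rate_ccw_to_cw else model$rate_cw_to_ccw
  m <- model$stimulus_rate_map
  if (is.null(m)) return(base)
  hit <- which(t >= m$t_start & t < m$t_end)
  if (length(hit) == 0L) return(base)
  over <- if (from_state == "CCW") m$rate_ccw_to_cw[hit[1L]] else m$rate_cw_to_ccw[hit[1L]]
  if (is.infinite(model$adapt_tau_s)) return(over)
  base + (over - base) * exp(-(t - m$t_start[hit[1L]]) / model$adapt_tau_s)
}

# Upper bound on the switching rate out of `from_state` over all times;
# used as the thinning envelope.
switch_rate_bound <- function(model, from_state) {
  base <- if (from_state == "CCW") model$rate_ccw_to_cw else model$rate_cw_to_ccw
  m <- model$stimulus_rate_map
  if (is.null(m)) return(base)
  over <- if (from_state == "CCW") m$rate_ccw_to_cw else m$rate_cw_to_ccw
  max(base, over)
}

#' Map observed switching statistics to model rates
#'
#' Inverts the stationary relations of the two-state model: for switching
#' rates a (CCW to CW) and b (CW to CCW), the stationary CW bias is
#' a / (a + b) and the stationary reversal (switch) rate is 2ab / (a + b).
#' Given a target reversal rate and CW bias this returns the unique (a, b).
#'
#' @param reversals_per_min Target stationary reversal rate (reversals/min).
#' @param cw_bias Target stationary CW bias, strictly inside (0, 1).
#' @return Named list with elements `rate_ccw_to_cw` and `rate_cw_to_ccw`
#'   (events/s).
#' @export
rates_from_statistics <- function(reversals_per_min, cw_bias) {
  if (cw_bias <= 0 || cw_bias >= 1)
    stop("cw_bias must lie strictly inside (0, 1)", call. = FALSE)
  if (reversals_per_min <= 0) stop("reversals_per_min must be > 0", call. = FALSE)
  r <- reversals_per_min / 60               # events/s
  total <- r / (2 * cw_bias * (1 - cw_bias))  # a + b
  list(rate_ccw_to_cw = cw_bias * total,
       rate_cw_to_ccw = (1 - cw_bias) * total)
}

#' Preset switching models for the study conditions
#'
#' Presets encode the observable motor statistics of each experimental
#' condition (stationary reversal rate and CW bias) mapped to two-state
#' switching rates via [rates_from_statistics()]. Stimulus responses are
#' time-windowed rate overrides starting at the stimulus time, relaxing
#' back to baseline with the model's adaptation constant.
#'
#' * `wt_baseline`: unstimulated wild type; 39.07 reversals/min at CW bias
#'   0.15, predominantly CCW rotation.
#' * `wt_peroxide`: wild type exposed to a saturating oxidant at 60 s;
#'   the post-stimulus window (60 s long, after which beads typically
#'   detach) runs at 64.53 reversals/min, CW bias 0.35 (repellent).
#' * `aer_null`: receptor-deletion control; the stimulus window carries the
#'   unchanged baseline rates, i.e. no response.
#' * `kanamycin_biphasic`: attractant phase (25 reversals/min, bias 0.08)
#'   immediately after drug addition at 60 s, switching to a repellent
#'   phase (64.53 reversals/min, bias 0.35) from 6 min after addition to
#'   the end of a 10-min post window.
#'
#' @param name One of `"wt_baseline"`, `"wt_peroxide"`, `"aer_null"`,
#'   `"kanamycin_biphasic"`.
#' @param stimulus_time_s Stimulus addition time (s); the baseline recording
#'   precedes it. Default 60 s.
#' @param speed_hz Bead orbit speed (revolutions/s).
#' @return A `switching_model` with attributes `preset`, `stimulus_time_s`
#'   and `recommended_duration_s`.
#' @export
preset_switching_model <- function(name = c("wt_baseline", "wt_peroxide",
                                            "aer_null", "kanamycin_biphasic"),
                                   stimulus_time_s = 60, speed_hz = 50) {
  name <- match.arg(name)
  base <- rates_from_statistics(39.07, 0.15)
  rep_rates <- rates_from_statistics(64.53, 0.35)
  att_rates <- rates_from_statistics(25, 0.08)
  t0 <- stimulus_time_s
  map <- NULL
  dur <- t0 + 60
  if (name == "wt_peroxide") {
    map <- data.frame(t_start = t0, t_end = t0 + 60,
                      rate_ccw_to_cw = rep_rates$rate_ccw_to_cw,
                      rate_cw_to_ccw = rep_rates$rate_cw_to_ccw)
  } else if (name == "aer_null") {
    map <- data.frame(t_start = t0, t_end = t0 + 60,
                      rate_ccw_to_cw = base$rate_ccw_to_cw,
                      rate_cw_to_ccw = base$rate_cw_to_ccw)
  } else if (name == "kanamycin_biphasic") {
    map <- data.frame(t_start = c(t0, t0 + 360),
                      t_end = c(t0 + 360, t0 + 600),
                      rate_ccw_to_cw = c(att_rates$rate_ccw_to_cw,
                                         rep_rates$rate_ccw_to_cw),
                      rate_cw_to_ccw = c(att_rates$rate_cw_to_ccw,
                                         rep_rates$rate_cw_to_ccw))
    dur <- t0 + 600
  }
  m <- switching_model(base$rate_ccw_to_cw, base$rate_cw_to_ccw,
                       speed_hz = speed_hz, stimulus_rate_map = map)
  attr(m, "preset") <- name
  attr(m, "stimulus_time_s") <- t0
  attr(m, "recommended_duration_s") <- dur
  m
}

#' @export
print.switching_model <- function(x, ...) {
  cat("Two-state motor switching model\n")
  cat(sprintf("  CCW->CW rate : %.4g /s\n", x$rate_ccw_to_cw))
  cat(sprintf("  CW->CCW rate : %.4g /s\n", x$rate_cw_to_ccw))
  cat(sprintf("  orbit speed  : %.4g Hz\n", x$speed_hz))
  if (x$rate_ccw_to_cw + x$rate_cw_to_ccw > 0)
    cat(sprintf("  stationary CW bias: %.3f\n", stationary_cw_bias(x)))
  if (!is.null(x$stimulus_rate_map))
    cat(sprintf("  stimulus windows  : %d (adaptation tau %.4g s)\n",
                nrow(x$stimulus_rate_map), x$adapt_tau_s))
  invisible(x)
}
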