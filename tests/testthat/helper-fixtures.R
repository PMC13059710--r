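# Shared fixtures built in code.

# A noiseless circular trajectory rotating CCW (mathematical convention,
# increasing angle) at `speed_hz`, switching to CW at `switch_at` if given.
make_circle_trace <- function(duration_s, fps, speed_hz, radius = 0.25,
                              switch_at = NULL, center = c(1, -2)) {
  t <- (seq_len(duration_s * fps) - 1L) / fps
  if (is.null(switch_at)) {
    theta <- 2 * pi * speed_hz * t
  } else {
    theta <- ifelse(t < switch_at,
                    2 * pi * speed_hz * t,
                    2 * pi * speed_hz * (2 * switch_at - t))
  }
  tr <- data.frame(time_s = t,
                   x_um = center[1] + radius * cos(theta),
                   y_um = center[2] + radius * sin(theta))
  class(tr) <- c("motor_trace", "data.frame")
  attr(tr, "fps") <- fps
  tr
}

# A direction series built directly from a label vector (for the counting
# and bias primitives).
make_direction_series <- function(states, fps = 100, speed_hz = 25) {
  n <- length(states)
  speed <- c(CCW = -speed_hz, CW = speed_hz, PAUSE = 0)[states]
  ds <- data.frame(time_s = (seq_len(n) - 1L) / fps, state = states,
                   signed_speed_hz = unname(speed), stringsAsFactors = FALSE)
  class(ds) <- c("direction_series", "data.frame")
  attr(ds, "fps") <- fps
  ds
}

# Brute-force discrete-time oracle for the two-state switching process:
# fine-step chain with per-step switch probability rate*dt. Returns the
# number of switch events.
discrete_time_switch_oracle <- function(rate_a, rate_b, duration_s,
                                        dt = 1e-4, init_cw = FALSE) {
  n <- round(duration_s / dt)
  u <- stats::runif(n)
  state <- logical(n) # TRUE = CW
  cur <- init_cw
  events <- 0L
  p_a <- rate_a * dt
  p_b <- rate_b * dt
  for (i in seq_len(n)) {
    p <- if (cur) p_b else p_a
    if (u[i] < p) {
      cur <- !cur
      events <- events + 1L
    }
  }
  events
}
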