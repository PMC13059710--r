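test_that("rotation estimation recovers speed, chirality, and switch timing", {
  # noiseless CCW orbit at 50 Hz -> signed speed -50 Hz (CCW negative)
  tr <- make_circle_trace(5, 1000, 50)
  rot <- estimate_rotation(tr)
  inner <- 100:4900
  expect_true(all(abs(rot$signed_speed_hz[inner] + 50) < 0.5))

  # mirroring y flips the apparent chirality
  tr2 <- tr
  tr2$y_um <- -tr2$y_um
  rot2 <- estimate_rotation(tr2)
  expect_true(all(abs(rot2$signed_speed_hz[inner] - 50) < 0.5))

  # the image_y_down flag undoes screen-coordinate chirality
  rot3 <- estimate_rotation(tr2, image_y_down = TRUE)
  expect_equal(rot3$signed_speed_hz[inner], rot$signed_speed_hz[inner],
               tolerance = 1e-6)

  # a single CCW->CW switch is located within +/- 5 ms
  trs <- make_circle_trace(60, 1000, 50, switch_at = 30)
  ds <- classify_direction(estimate_rotation(trs))
  first_cw <- ds$time_s[match("CW", ds$state)]
  expect_lt(abs(first_cw - 30), 0.005)

  # degenerate zero-radius trace fails loudly
  trz <- data.frame(time_s = (0:99) / 100, x_um = rep(1, 100), y_um = rep(2, 100))
  expect_error(suppressWarnings(estimate_rotation(trz)), "degenerate|radius")
})

test_that("direction classification thresholds, debounces, and flags degenerate output", {
  fps <- 200
  t <- (0:(10 * fps - 1)) / fps
  v <- rep(10, length(t))
  rot <- data.frame(time_s = t, signed_speed_hz = v)
  ds <- classify_direction(rot, pause_threshold_hz = 2)
  expect_true(all(ds$state == "CW"))

  # alternating +/-10 Hz each second, no pauses after debounce
  v2 <- ifelse(floor(t) %% 2 == 0, 10, -10)
  ds2 <- classify_direction(data.frame(time_s = t, signed_speed_hz = v2),
                            min_dwell_s = 0.05)
  expect_setequal(unique(ds2$state), c("CW", "CCW"))

  # a 2-frame blip is merged into the flanking state
  v3 <- rep(10, length(t)); v3[500:501] <- -10
  ds3 <- classify_direction(data.frame(time_s = t, signed_speed_hz = v3),
                            min_dwell_s = 0.05)
  expect_true(all(ds3$state == "CW"))

  # all-pause output is allowed but flagged
  expect_warning(
    ds4 <- classify_direction(data.frame(time_s = t,
                                         signed_speed_hz = rep(0, length(t)))),
    "PAUSE")
  expect_true(attr(ds4, "degenerate"))
})

test_that("CW bias is the CW fraction of direction-labelled frames", {
  ds <- make_direction_series(rep("CCW", 50))
  expect_identical(compute_cw_bias(ds), 0)
  ds2 <- make_direction_series(c(rep("CW", 3), rep("CCW", 7)))
  expect_identical(compute_cw_bias(ds2), 0.3)
  # pauses drop out of numerator and denominator
  ds3 <- make_direction_series(c(rep("CW", 3), rep("PAUSE", 40), rep("CCW", 3)))
  expect_identical(compute_cw_bias(ds3), 0.5)
  ds4 <- make_direction_series(rep("PAUSE", 10))
  expect_error(compute_cw_bias(ds4), "undefined")
})

test_that("running-average CW bias behaves as a centered moving window", {
  # constant direction -> constant smoothed series
  ds <- make_direction_series(rep("CW", 4000), fps = 100)
  sm <- smooth_cw_bias(ds, window_s = 30)
  expect_true(all(sm$cw_bias == 1))

  # step from all-CCW to all-CW: smoothed bias is monotone nondecreasing
  ds2 <- make_direction_series(c(rep("CCW", 3000), rep("CW", 3000)), fps = 100)
  sm2 <- smooth_cw_bias(ds2, window_s = 30)
  expect_true(all(diff(sm2$cw_bias) >= -1e-12))
  expect_equal(sm2$cw_bias[1], 0)
  expect_equal(sm2$cw_bias[nrow(sm2)], 1)

  # smoothed mean agrees with the whole-window bias on stationary traces
  m <- switching_model(0.6, 1.4, speed_hz = 25)
  diffs <- vapply(1:50, function(s) {
    sim <- simulate_motor_trace(m, 60, fps = 100, seed = s,
                                position_noise_sd_um = 0)
    mean(smooth_cw_bias(sim$truth)$cw_bias, na.rm = TRUE) -
      compute_cw_bias(sim$truth)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-3)

  # short recordings fall back to a single whole-trace value with a warning
  ds5 <- make_direction_series(rep(c("CW", "CCW"), 100), fps = 100)
  expect_warning(sm5 <- smooth_cw_bias(ds5, window_s = 30), "shorter")
  expect_identical(nrow(sm5), 1L)
  expect_equal(sm5$cw_bias, 0.5)
})

test_that("reversal counting uses debounced transitions with pause bridging", {
  # constant direction -> 0/min
  expect_equal(as.numeric(count_reversals(make_direction_series(rep("CW", 600)))), 0)

  # strict alternation every 1 s for 60 s -> 59 transitions -> 59/min
  states <- rep(rep(c("CW", "CCW"), 30), each = 100)
  ds <- make_direction_series(states, fps = 100)
  expect_equal(as.numeric(count_reversals(ds)), 59)

  # pause-bridged transitions count once; pause-and-return counts zero
  ds_b <- make_direction_series(c(rep("CCW", 100), rep("PAUSE", 100), rep("CW", 100)))
  expect_identical(attr(count_reversals(ds_b), "n_reversals"), 1L)
  ds_r <- make_direction_series(c(rep("CCW", 100), rep("PAUSE", 100), rep("CCW", 100)))
  expect_identical(attr(count_reversals(ds_r), "n_reversals"), 0L)

  expect_error(count_reversals(ds, window = c(0, 0.5)), "1 s")
})

test_that("reversal counts are invariant to temporal subsampling on clean traces", {
  m <- switching_model(0.1, 0.15, speed_hz = 10)
  sim <- simulate_motor_trace(m, 120, fps = 1000, seed = 11,
                              position_noise_sd_um = 0)
  count_at <- function(step) {
    tr <- sim$trace[seq(1, nrow(sim$trace), by = step), ]
    class(tr) <- c("motor_trace", "data.frame")
    attr(tr, "fps") <- 1000 / step
    ds <- classify_direction(estimate_rotation(tr))
    attr(count_reversals(ds), "n_reversals")
  }
  full <- count_at(1)
  expect_identical(count_at(2), full)   # 500 fps
  expect_identical(count_at(10), full)  # 100 fps
})

test_that("estimated statistics inherit the model's invariance and scaling", {
  # doubling both switching rates doubles the reversal rate, CW bias unchanged
  m1 <- switching_model(0.3, 0.7, speed_hz = 25)
  m2 <- switching_model(0.6, 1.4, speed_hz = 25)
  stat <- function(m) {
    res <- vapply(1:60, function(s) {
      p <- simulate_switch_path(m, 120, seed = s)
      cw <- p$state == "CW"
      c(attr(p, "n_reversals") / 2, sum((p$t_end - p$t_start)[cw]) / 120)
    }, numeric(2))
    list(rate = res[1, ], bias = res[2, ])
  }
  s1 <- stat(m1); s2 <- stat(m2)
  se_rate <- sqrt(var(s2$rate) / 60 + 4 * var(s1$rate) / 60)
  expect_lt(abs(mean(s2$rate) - 2 * mean(s1$rate)), 3 * se_rate)
  se_bias <- sqrt(var(s1$bias) / 60 + var(s2$bias) / 60)
  expect_lt(abs(mean(s1$bias) - mean(s2$bias)), 3 * se_bias)
})

test_that("pre/post comparison reproduces the Student's t-test and reports group summaries", {
  res <- compare_pre_post(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(res$mean_pre, 2)
  expect_equal(res$sem_pre, 1 / sqrt(3))

  same <- compare_pre_post(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_pre_post(1, c(1, 2)), "insufficient")

  # metric extraction from motor summaries
  ds <- make_direction_series(rep(rep(c("CW", "CCW"), 30), each = 100), fps = 100)
  s <- summarize_motor(ds)
  expect_equal(s$cw_bias, 0.5)
  expect_equal(s$reversal_rate_per_min, 59)
  res2 <- compare_pre_post(list(s, s, s), c(59, 59, 60.5),
                           metric = "reversal_rate_per_min")
  expect_true(is.finite(res2$p_value))
})

test_that("simulated-motor recovery: classification agrees with ground truth and a repellent shift is detected", {
  m <- switching_model(0.65, 0.65, speed_hz = 25)
  agree <- vapply(1:10, function(s) {
    sim <- simulate_motor_trace(m, 60, fps = 250, seed = s,
                                position_noise_sd_um = 0.02)
    ds <- classify_direction(estimate_rotation(sim$trace))
    mean(ds$state == sim$truth$state)
  }, numeric(1))
  expect_gt(mean(agree), 0.99)

  # power: baseline vs doubled-rate groups separate at p < 0.01
  m2 <- switching_model(1.3, 1.3, speed_hz = 25)
  detected <- vapply(1:40, function(r) {
    g1 <- vapply(1:8, function(i)
      attr(simulate_switch_path(m, 120, seed = 1000 * r + i), "n_reversals") / 2,
      numeric(1))
    g2 <- vapply(1:8, function(i)
      attr(simulate_switch_path(m2, 120, seed = 5e5 + 1000 * r + i), "n_reversals") / 2,
      numeric(1))
    compare_pre_post(g1, g2)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})
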