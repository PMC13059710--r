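test_that("bi-exponential bleach fitting recovers well-separated decay parameters", {
  t <- seq(0, 600, by = 0.05)
  truth <- bleach_model(amp1 = 0.6, tau1 = 50, tau2 = 500)
  y <- 1200 * bleach_decay(truth, t)
  fit <- fit_bleach_correction(t, y)
  expect_identical(fit$convergence, "converged")
  expect_lt(abs(fit$model$amp1 - 0.6) / 0.6, 0.01)
  expect_lt(abs(fit$model$tau1 - 50) / 50, 0.01)
  expect_lt(abs(fit$model$tau2 - 500) / 500, 0.01)
  expect_lt(abs(fit$i0 - 1200) / 1200, 0.01)
  # the corrected trace is flat at the unbleached amplitude
  expect_lt(max(abs(fit$corrected - 1200)), 1e-6 * 1200)
})

test_that("bleach fitting handles constant channels and exclusion windows", {
  t <- seq(0, 100, by = 0.1)
  fit <- fit_bleach_correction(t, rep(500, length(t)))
  expect_identical(fit$convergence, "degenerate-constant")
  expect_equal(fit$corrected, rep(500, length(t)))

  # a signal transient inside an excluded window does not bend the decay
  truth <- bleach_model(amp1 = 0.5, tau1 = 40, tau2 = 400)
  y <- 800 * bleach_decay(truth, t)
  y[t >= 30 & t < 50] <- y[t >= 30 & t < 50] * 0.6   # stimulus response
  fit2 <- fit_bleach_correction(t, y, exclude_windows = data.frame(t_start = 30,
                                                                   t_end = 50))
  expect_lt(abs(fit2$model$tau1 - 40) / 40, 0.02)
  expect_lt(abs(fit2$model$tau2 - 400) / 400, 0.02)

  expect_error(fit_bleach_correction(t[1:30], y[1:30]), "at least 50")
})

test_that("corrected constant-signal traces carry no residual slope", {
  t <- seq(0, 600, by = 0.05)
  truth <- bleach_model(amp1 = 0.4, tau1 = 60, tau2 = 800)
  withr::with_seed(3, {
    y <- 1000 * bleach_decay(truth, t) * (1 + rnorm(length(t), 0, 0.01))
  })
  fit <- fit_bleach_correction(t, y)
  lm_fit <- lm(fit$corrected ~ t)
  ci <- confint(lm_fit)["t", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("optical constants are recovered from single-label controls and bleach pairs", {
  const <- efret_constants(a = 0.08, d = 0.12, G = 2.0)
  sch <- stimulus_schedule(duration_s = 60)
  # acceptor-only: no donor fluorophore
  acc <- simulate_fret_experiment(kinase_step_model(baseline_activity = 0),
                                  bleach_model(0, 1, Inf), bleach_model(0, 1, Inf),
                                  const, sch, i0_donor = 0, shot_noise_sd = 0.01,
                                  seed = 1)
  # donor-only: no acceptor, zero transfer
  don <- simulate_fret_experiment(kinase_step_model(baseline_activity = 0,
                                                    e_min = 0, e_max = 0.3),
                                  bleach_model(0, 1, Inf), bleach_model(0, 1, Inf),
                                  const, sch, i0_acceptor = 0, shot_noise_sd = 0.01,
                                  seed = 2)
  cal <- calibrate_constants(acc, don, G = 2.0)
  expect_equal(cal$a, 0.08, tolerance = 0.02)
  expect_equal(cal$d, 0.12, tolerance = 0.02)
  expect_identical(attr(cal, "g_provenance"), "config")

  # zero cross-talk controls give a = d = 0
  const0 <- efret_constants(a = 0, d = 0, G = 2.0)
  acc0 <- simulate_fret_experiment(kinase_step_model(baseline_activity = 0),
                                   bleach_model(0, 1, Inf), bleach_model(0, 1, Inf),
                                   const0, sch, i0_donor = 0, shot_noise_sd = 0,
                                   seed = 3)
  don0 <- simulate_fret_experiment(kinase_step_model(baseline_activity = 0,
                                                     e_min = 0, e_max = 0.3),
                                   bleach_model(0, 1, Inf), bleach_model(0, 1, Inf),
                                   const0, sch, i0_acceptor = 0, shot_noise_sd = 0,
                                   seed = 4)
  cal0 <- calibrate_constants(acc0, don0, G = 2.0)
  expect_equal(cal0$a, 0)
  expect_equal(cal0$d, 0)

  # G from an acceptor-photobleach pair: E = 0.25 before, acceptor dark
  # after; the pair shares the cross-talk-free constants used for a and d
  k_on <- kinase_step_model(baseline_activity = 1, e_min = 0, e_max = 0.25)
  const_g <- efret_constants(a = 0, d = 0, G = 2.0)
  pre <- simulate_fret_experiment(k_on, bleach_model(0, 1, Inf),
                                  bleach_model(0, 1, Inf), const_g, sch,
                                  shot_noise_sd = 0, seed = 5)
  post <- simulate_fret_experiment(kinase_step_model(baseline_activity = 0,
                                                     e_min = 0, e_max = 0.25),
                                   bleach_model(0, 1, Inf), bleach_model(0, 1, Inf),
                                   const_g, sch, i0_acceptor = 0, shot_noise_sd = 0,
                                   seed = 6)
  cal_g <- calibrate_constants(acc0, don0, G = list(pre = pre, post = post))
  expect_equal(cal_g$G, 2.0, tolerance = 1e-10)
  expect_identical(attr(cal_g, "g_provenance"), "acceptor-photobleach-pair")
})

test_that("E-FRET algebraic identities hold frame by frame", {
  n <- 50
  t <- (seq_len(n) - 1) * 0.05
  G <- 1.6
  const <- efret_constants(a = 0, d = 0, G = G)
  # a = d = 0 and IDA = G * IDD  ->  E_app = 1/2
  exp1 <- data.frame(time_s = t, IDD = rep(400, n), IDA = G * rep(400, n),
                     IAA = rep(300, n))
  ef1 <- compute_efret(exp1, const, warn_uncorrected = FALSE)
  expect_equal(ef1$e_app, rep(0.5, n))

  # IDA exactly equal to the bleed-through terms -> E_app = 0
  const2 <- efret_constants(a = 0.1, d = 0.15, G = 2)
  exp2 <- data.frame(time_s = t, IDD = rep(400, n), IAA = rep(300, n))
  exp2$IDA <- const2$a * exp2$IAA + const2$d * exp2$IDD
  ef2 <- compute_efret(exp2, const2, warn_uncorrected = FALSE)
  expect_equal(ef2$e_app, rep(0, n))

  # invariance to a common rescaling of all three channels
  exp3 <- simulate_fret_experiment(constants = const2, shot_noise_sd = 0.01,
                                   seed = 7)
  exp4 <- exp3
  for (ch in c("IDD", "IDA", "IAA")) exp4[[ch]] <- 3.7 * exp4[[ch]]
  e3 <- compute_efret(exp3, const2, warn_uncorrected = FALSE)$e_app
  e4 <- compute_efret(exp4, const2, warn_uncorrected = FALSE)$e_app
  expect_equal(e3, e4, tolerance = 1e-12)
})

test_that("denominator masking flags weak frames instead of returning spikes", {
  t <- (0:99) * 0.05
  const <- efret_constants(a = 0, d = 0, G = 2)
  IDD <- rep(500, 100)
  IDA <- rep(100, 100)
  IDA[50] <- -2 * IDD[50] + 1e-9   # denominator ~ 0 at one frame
  exp <- data.frame(time_s = t, IDD = IDD, IDA = IDA, IAA = rep(0, 100))
  ef <- compute_efret(exp, const, warn_uncorrected = FALSE)
  expect_true(is.na(ef$e_app[50]))
  expect_identical(attr(ef, "n_masked"), 1L)
})

test_that("min-max normalization maps saturating windows to 0 and 1 and is affine-invariant", {
  sch <- default_fret_schedule(600)
  exp <- simulate_fret_experiment(schedule = sch, shot_noise_sd = 0)
  ef <- compute_efret(exp, efret_constants(), warn_uncorrected = FALSE)
  act <- normalize_activity(ef, sch)
  w <- sch$saturating_windows
  in_win <- function(i) ef$time_s >= w$t_start[i] & ef$time_s < w$t_end[i]
  expect_equal(mean(act$activity[in_win(1)]), 1)   # max window
  expect_equal(mean(act$activity[in_win(2)]), 0)   # min window
  truth <- attr(exp, "truth")$activity
  expect_lt(sqrt(mean((act$activity - truth)^2)), 1e-10)

  # invariance to positive affine transforms of E
  ef2 <- ef
  ef2$e_app <- 2.5 * ef$e_app + 0.3
  act2 <- normalize_activity(ef2, sch)
  expect_equal(act2$activity, act$activity, tolerance = 1e-10)

  # inverted windows are rejected
  w_bad <- data.frame(t_start = w$t_start, t_end = w$t_end,
                      extreme = rev(w$extreme))
  sch_bad <- stimulus_schedule(saturating_windows = w_bad, duration_s = 600)
  expect_error(normalize_activity(ef, sch_bad), "normalization failure")
})

test_that("adaptation-time estimation matches step constructions and flags non-responders", {
  dt <- 0.1
  t <- seq(0, 299.9, by = dt)
  # exact step back to baseline at t_stim + 60 s
  a <- rep(0.3, length(t))
  a[t >= 120 & t < 180] <- 0.8
  act <- data.frame(time_s = t, activity = a)
  res <- estimate_adaptation_time(act, stimulus_time_s = 120, smooth_s = 0)
  expect_identical(res$flag, "ok")
  expect_equal(res$adaptation_time_s, 60, tolerance = 2 * dt)
  # the default 1-s smoothing shifts re-entry by at most half its window
  res_sm <- estimate_adaptation_time(act, stimulus_time_s = 120)
  expect_equal(res_sm$adaptation_time_s, 60, tolerance = 1)

  # flat trace: no response
  flat <- data.frame(time_s = t, activity = rep(0.3, length(t)))
  res2 <- estimate_adaptation_time(flat, stimulus_time_s = 120)
  expect_identical(res2$flag, "no-response")
  expect_true(is.na(res2$adaptation_time_s))

  # exponential adaptation with tau = 20 s at default noise: the band
  # re-entry criterion predicts a crossing between 2 and 5 tau
  k <- kinase_step_model(adaptation_tau_s = 20)
  exp <- simulate_fret_experiment(k, schedule = default_fret_schedule(600),
                                  shot_noise_sd = 0.01, seed = 12)
  out <- analyze_fret_experiment(exp, efret_constants())
  expect_identical(out$summary$flag, "ok")
  expect_gte(out$summary$adaptation_time_s, 2 * 20)
  expect_lte(out$summary$adaptation_time_s, 5 * 20)
})

test_that("the full pipeline recovers ground-truth activity under bleaching and noise", {
  rmse <- vapply(1:8, function(s) {
    exp <- simulate_fret_experiment(seed = s)
    out <- analyze_fret_experiment(exp, efret_constants())
    truth <- attr(exp, "truth")$activity
    sqrt(mean((out$activity$activity - truth)^2, na.rm = TRUE))
  }, numeric(1))
  expect_lt(mean(rmse), 0.02)
})
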