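#' Fit and apply a bi-exponential photobleaching correction
#'
#' Fits `I(t) = I0 * (A * exp(-t/tau1) + (1-A) * exp(-t/tau2))` to a channel
#' by bounded Levenberg-Marquardt least squares, then divides the raw trace
#' by the normalized decay. Frames inside `exclude_windows` (stimulus
#' responses, saturating windows) are excluded from the fit so that genuine
#' signal changes are not absorbed into the decay, but the correction is
#' applied to every frame.
#'
#' @param t Time grid (s).
#' @param intensity Channel intensities (counts), same length as `t`.
#' @param exclude_windows Optional data frame (`t_start`, `t_end`) of
#'   windows excluded from the fit.
#' @param min_fit_frames Minimum number of frames that must remain for the
#'   fit (default 50).
#' @return A `bleach_fit` list: `model` (a [bleach_model()]), `i0`,
#'   `corrected` (intensities divided by the fitted decay), `decay`
#'   (fitted decay on `t`), `convergence` (`"converged"` or
#'   `"degenerate-constant"`), and `residual_sd`.
#' @export
fit_bleach_correction <- function(t, intensity, exclude_windows = NULL,
                                  min_fit_frames = 50) {
  stopifnot(length(t) == length(intensity))
  keep <- rep(TRUE, length(t))
  if (!is.null(exclude_windows)) {
    w <- as.data.frame(exclude_windows)
    for (i in seq_len(nrow(w)))
      keep <- keep & !(t >= w$t_start[i] & t < w$t_end[i])
  }
  if (sum(keep) < min_fit_frames)
    stop(sprintf("need at least %d frames outside excluded windows (have %d)",
                 min_fit_frames, sum(keep)), call. = FALSE)
  tf <- t[keep]; yf <- intensity[keep]
  m0 <- mean(yf)
  if (m0 <= 0) stop("channel has non-positive mean; cannot fit bleaching",
                    call. = FALSE)
  # a flat channel carries no decay information: identity correction
  if (stats::sd(yf) / m0 < 1e-8) {
    out <- list(model = bleach_model(amp1 = 1, tau1 = Inf, tau2 = Inf),
                i0 = m0, corrected = intensity,
                decay = rep(1, length(t)),
                convergence = "degenerate-constant", residual_sd = 0)
    class(out) <- "bleach_fit"
    return(out)
  }
  span <- max(tf) - min(tf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yf ~ I0 * (A * exp(-tf / tau1) + (1 - A) * exp(-tf / tau2)),
      start = list(I0 = max(yf), A = 0.5, tau1 = span / 10, tau2 = span),
      lower = c(I0 = 0, A = 0, tau1 = 1e-6, tau2 = 1e-6),
      upper = c(I0 = Inf, A = 1, tau1 = Inf, tau2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf("photobleach fit failed to converge: %s (channel mean %.4g, CV %.3g)",
                 conditionMessage(fit), m0, stats::sd(yf) / m0), call. = FALSE)
  }
  p <- as.list(stats::coef(fit))
  if (p$tau1 > p$tau2) {   # canonical order: tau1 is the fast component
    p <- list(I0 = p$I0, A = 1 - p$A, tau1 = p$tau2, tau2 = p$tau1)
  }
  model <- bleach_model(amp1 = p$A, tau1 = p$tau1, tau2 = p$tau2)
  decay <- bleach_decay(model, t)
  out <- list(model = model, i0 = p$I0,
              corrected = intensity / decay, decay = decay,
              convergence = "converged",
              residual_sd = stats::sd(stats::resid(fit)))
  class(out) <- "bleach_fit"
  out
}

#' Photobleach-correct a three-channel FRET experiment
#'
#' Fits bi-exponential decays to the donor channel (IDD) and the acceptor
#' channel (IAA) and divides each by its fitted decay. The FRET channel IDA
#' mixes donor-derived sensitized emission with the two bleed-through
#' terms; when the optical constants are supplied, its donor-derived
#' component `IDA - a*IAA - d*IDD` is corrected by the donor decay and the
#' bleed-through terms are rebuilt from the corrected channels, otherwise
#' the whole channel is corrected by the donor decay.
#'
#' @param exp A `fret_experiment`.
#' @param constants Optional [efret_constants()] enabling the
#'   component-wise IDA correction.
#' @param exclude_windows Optional data frame (`t_start`, `t_end`) excluded
#'   from the decay fits; defaults to [default_exclude_windows()] of the
#'   experiment's schedule when one is attached.
#' @return A corrected `fret_experiment` (attribute `corrected = TRUE`)
#'   with attribute `bleach_fits` (list with `donor`, `acceptor`).
#' @export
correct_fret_channels <- function(exp, constants = NULL,
                                  exclude_windows = NULL) {
  stopifnot(inherits(exp, "fret_experiment") ||
              all(c("time_s", "IDD", "IDA", "IAA") %in% names(exp)))
  schedule <- attr(exp, "schedule")
  if (is.null(exclude_windows) && !is.null(schedule))
    exclude_windows <- default_exclude_windows(schedule)
  fit_d <- fit_bleach_correction(exp$time_s, exp$IDD, exclude_windows)
  fit_a <- fit_bleach_correction(exp$time_s, exp$IAA, exclude_windows)
  IDDc <- fit_d$corrected
  IAAc <- fit_a$corrected
  if (!is.null(constants)) {
    stopifnot(inherits(constants, "efret_constants"))
    sens <- exp$IDA - constants$a * exp$IAA - constants$d * exp$IDD
    IDAc <- sens / fit_d$decay + constants$a * IAAc + constants$d * IDDc
  } else {
    IDAc <- exp$IDA / fit_d$decay
  }
  out <- data.frame(time_s = exp$time_s, IDD = IDDc, IDA = IDAc, IAA = IAAc)
  class(out) <- c("fret_experiment", "data.frame")
  for (at in c("schedule", "cell_id", "constants", "truth"))
    attr(out, at) <- attr(exp, at)
  attr(out, "corrected") <- TRUE
  attr(out, "bleach_fits") <- list(donor = fit_d, acceptor = fit_a)
  out
}

#' Fit-exclusion windows implied by a stimulus schedule
#'
#' Saturating windows plus, for each stimulus event, the response transient
#' (five adaptation/recovery time constants after the event).
#'
#' @param schedule A [stimulus_schedule()].
#' @param adaptation_tau_s,recovery_tau_s Transient lengths assumed for
#'   `add` and `remove` events (s).
#' @return Data frame with columns `t_start`, `t_end`.
#' @export
default_exclude_windows <- function(schedule, adaptation_tau_s = 60,
                                    recovery_tau_s = 30) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  out <- data.frame(t_start = numeric(0), t_end = numeric(0))
  w <- schedule$saturating_windows
  if (!is.null(w)) out <- rbind(out, w[, c("t_start", "t_end")])
  ev <- schedule$events
  if (!is.null(ev)) {
    tau <- ifelse(ev$kind == "add", adaptation_tau_s, recovery_tau_s)
    out <- rbind(out, data.frame(t_start = ev$time_s,
                                 t_end = pmin(ev$time_s + 5 * tau,
                                              schedule$duration_s)))
  }
  out
}

#' Calibrate E-FRET optical constants from single-label controls
#'
#' On acceptor-only cells the donor channels are dark, so the FRET-channel
#' signal is pure direct-excitation bleed-through: `a = median(IDA / IAA)`.
#' On donor-only cells `d = median(IDA / IDD)`. The gauge factor `G` is
#' taken from configuration, or computed from paired recordings made before
#' and after acceptor photobleaching as the ratio of lost sensitized
#' emission to recovered donor emission,
#' `G = (IDA_sens_pre - IDA_sens_post) / (IDD_post - IDD_pre)`.
#'
#' @param acceptor_only,donor_only Lists of `fret_experiment`s (or single
#'   experiments) from single-label strains.
#' @param G Either a numeric gauge factor, or a list
#'   `list(pre = experiment, post = experiment)` of paired recordings
#'   bracketing acceptor photobleaching.
#' @return An [efret_constants()] with attribute `g_provenance`
#'   (`"config"` or `"acceptor-photobleach-pair"`).
#' @export
calibrate_constants <- function(acceptor_only, donor_only, G = 1.8) {
  as_list <- function(x) if (inherits(x, "fret_experiment") || is.data.frame(x)) list(x) else x
  acceptor_only <- as_list(acceptor_only)
  donor_only <- as_list(donor_only)
  if (length(acceptor_only) == 0L || length(donor_only) == 0L)
    stop("both single-label sets must be nonempty", call. = FALSE)
  ratio <- function(exps, num, den) {
    vals <- unlist(lapply(exps, function(e) {
      dd <- e[[den]]
      if (stats::median(dd) <= .Machine$double.eps)
        stop(sprintf("calibration failure: %s channel is ~0", den), call. = FALSE)
      e[[num]] / dd
    }))
    stats::median(vals)
  }
  a <- ratio(acceptor_only, "IDA", "IAA")
  d <- ratio(donor_only, "IDA", "IDD")
  if (is.numeric(G)) {
    prov <- "config"
    g <- G
  } else {
    stopifnot(is.list(G), all(c("pre", "post") %in% names(G)))
    pre <- G$pre; post <- G$post
    sens <- function(e) e$IDA - a * e$IAA - d * e$IDD
    d_idd <- mean(post$IDD) - mean(pre$IDD)
    if (abs(d_idd) <= .Machine$double.eps)
      stop("calibration failure: no donor dequenching across the bleach pair",
           call. = FALSE)
    g <- (mean(sens(pre)) - mean(sens(post))) / d_idd
    prov <- "acceptor-photobleach-pair"
  }
  out <- efret_constants(a = max(a, 0), d = max(d, 0), G = g)
  attr(out, "g_provenance") <- prov
  out
}

#' Apparent FRET efficiency by the E-FRET method
#'
#' Per-frame apparent efficiency
#' `E_app = (IDA - a*IAA - d*IDD) / (IDA - a*IAA + (G - d)*IDD)`.
#' Frames whose denominator magnitude falls below a floor (default
#' `1e-6 * median(IDD)`) are masked as `NA` rather than returned as spikes.
#'
#' @param exp A `fret_experiment`, bleach-corrected (a warning is issued
#'   when the experiment is flagged uncorrected).
#' @param constants An [efret_constants()].
#' @param denom_floor_frac Denominator floor as a fraction of the median
#'   donor-channel intensity. Default 1e-6.
#' @param warn_uncorrected Warn when the experiment is flagged as not
#'   bleach-corrected. Default TRUE.
#' @return Data frame `time_s`, `e_app` (NA at masked frames), attribute
#'   `n_masked`.
#' @export
compute_efret <- function(exp, constants, denom_floor_frac = 1e-6,
                          warn_uncorrected = TRUE) {
  stopifnot(inherits(constants, "efret_constants"),
            all(c("time_s", "IDD", "IDA", "IAA") %in% names(exp)))
  corrected <- attr(exp, "corrected")
  if (warn_uncorrected && isFALSE(corrected))
    warning("experiment is not flagged as bleach-corrected; E-FRET values may drift",
            call. = FALSE)
  num <- exp$IDA - constants$a * exp$IAA - constants$d * exp$IDD
  den <- exp$IDA - constants$a * exp$IAA + (constants$G - constants$d) * exp$IDD
  floor_abs <- denom_floor_frac * stats::median(exp$IDD)
  e <- num / den
  masked <- abs(den) < floor_abs
  e[masked] <- NA_real_
  if (all(masked))
    stop("signal too weak: every frame's E-FRET denominator fell below the floor",
         call. = FALSE)
  out <- data.frame(time_s = exp$time_s, e_app = e)
  attr(out, "n_masked") <- sum(masked)
  out
}

#' Normalize FRET efficiency to kinase activity
#'
#' Rescales each cell's efficiency between the mean FRET measured in the
#' saturating kinase-OFF and kinase-ON windows, so 0-1 spans kinase-OFF to
#' kinase-ON. For the CheY-mRFP/CheZ-mYFP pair, higher kinase activity
#' gives more CheY-P/CheZ interaction and hence higher FRET (default
#' `direction = "high_fret_on"`); the convention is configurable.
#'
#' @param efret Data frame from [compute_efret()] (`time_s`, `e_app`).
#' @param schedule A [stimulus_schedule()] with at least one `min` and one
#'   `max` saturating window.
#' @param direction `"high_fret_on"` (default) or `"low_fret_on"`.
#' @return A `kinase_activity` data frame (`time_s`, `activity` clipped to
#'   \[0, 1\]) with attributes `e_sat_min`, `e_sat_max`.
#' @export
normalize_activity <- function(efret, schedule,
                               direction = c("high_fret_on", "low_fret_on")) {
  direction <- match.arg(direction)
  stopifnot(inherits(schedule, "stimulus_schedule"),
            all(c("time_s", "e_app") %in% names(efret)))
  w <- schedule$saturating_windows
  if (is.null(w) || !all(c("min", "max") %in% w$extreme))
    stop("schedule must contain at least one 'min' and one 'max' saturating window",
         call. = FALSE)
  win_mean <- function(extreme) {
    idx <- rep(FALSE, nrow(efret))
    for (i in which(w$extreme == extreme))
      idx <- idx | (efret$time_s >= w$t_start[i] & efret$time_s < w$t_end[i])
    mean(efret$e_app[idx], na.rm = TRUE)
  }
  e_lo <- win_mean("min")
  e_hi <- win_mean("max")
  if (direction == "low_fret_on") { tmp <- e_lo; e_lo <- e_hi; e_hi <- tmp }
  if (!(e_hi > e_lo))
    stop("normalization failure: saturating-window FRET levels are inverted or equal (windows likely mislabeled)",
         call. = FALSE)
  act <- pmin(pmax((efret$e_app - e_lo) / (e_hi - e_lo), 0), 1)
  out <- data.frame(time_s = efret$time_s, activity = act)
  class(out) <- c("kinase_activity", "data.frame")
  attr(out, "e_sat_min") <- e_lo
  attr(out, "e_sat_max") <- e_hi
  out
}

#' Adaptation time of a kinase-activity response
#'
#' The baseline is the mean activity over the pre-stimulus window. The
#' adaptation time is the first time after the post-stimulus extremum at
#' which activity re-enters the band baseline +/- k * SD(baseline) and
#' stays inside it for at least `hold_s` seconds, measured from the
#' stimulus.
#'
#' @param activity A `kinase_activity` data frame.
#' @param stimulus_time_s Stimulus time (s); at least 10 s of pre-stimulus
#'   baseline is required.
#' @param k Band half-width in baseline SDs. Default 2.
#' @param hold_s Time activity must remain inside the band (s). Default 5.
#' @param smooth_s Centered running-mean window applied to the activity
#'   before the band test (s); the peak and the baseline statistics use the
#'   raw series. Default 1; 0 disables smoothing. Without smoothing, frame
#'   noise alone keeps a 20 Hz series from staying inside a +/- 2 SD band
#'   for several seconds.
#' @param min_response Minimum post-stimulus deviation from baseline for a
#'   response to be declared (activity units). Default 0.05.
#' @return List with `baseline`, `baseline_sd`, `peak_time_s`,
#'   `peak_activity`, `adaptation_time_s` (NA when undefined), and
#'   `flag` (`"ok"`, `"no-response"`, or `"never-readapted"`).
#' @export
estimate_adaptation_time <- function(activity, stimulus_time_s, k = 2,
                                     hold_s = 5, smooth_s = 1,
                                     min_response = 0.05) {
  stopifnot(all(c("time_s", "activity") %in% names(activity)))
  t <- activity$time_s
  a <- activity$activity
  pre <- t < stimulus_time_s
  if (sum(pre) == 0L || (stimulus_time_s - t[1L]) < 10)
    stop("need at least 10 s of pre-stimulus baseline", call. = FALSE)
  base <- mean(a[pre], na.rm = TRUE)
  bsd <- stats::sd(a[pre], na.rm = TRUE)
  if (is.na(bsd)) bsd <- 0
  post <- which(t >= stimulus_time_s)
  dev <- a[post] - base
  i_ext <- post[which.max(abs(dev))]
  peak_dev <- max(abs(dev), na.rm = TRUE)
  if (peak_dev < max(k * bsd, min_response)) {
    return(list(baseline = base, baseline_sd = bsd, peak_time_s = NA_real_,
                peak_activity = NA_real_, adaptation_time_s = NA_real_,
                flag = "no-response"))
  }
  band <- k * bsd + 1e-9   # numeric floor so a zero-noise band is attainable
  dt <- stats::median(diff(t))
  a_s <- if (smooth_s > 0) rolling_mean(a, max(1L, round(smooth_s / dt))) else a
  inside <- abs(a_s - base) <= band & !is.na(a_s)
  hold_frames <- max(1L, round(hold_s / dt))
  n <- length(t)
  adaptation <- NA_real_
  flag <- "never-readapted"
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= hold_frames & ends > i_ext)
  if (length(ok) > 0L) {
    i0 <- max(starts[ok[1L]], i_ext + 1L)
    # the qualifying run must still hold for hold_s beyond the entry point
    if (ends[ok[1L]] - i0 + 1L >= hold_frames) {
      adaptation <- t[i0] - stimulus_time_s
      flag <- "ok"
    } else if (length(ok) > 1L) {
      i0 <- starts[ok[2L]]
      adaptation <- t[i0] - stimulus_time_s
      flag <- "ok"
    }
  }
  list(baseline = base, baseline_sd = bsd,
       peak_time_s = t[i_ext], peak_activity = a[i_ext],
       adaptation_time_s = adaptation, flag = flag)
}

#' Run the full FRET pipeline on one cell
#'
#' Bleach correction, E-FRET computation, per-cell min-max normalization,
#' and adaptation-time estimation for the first `add` event in the
#' schedule.
#'
#' @param exp A raw `fret_experiment`.
#' @param constants An [efret_constants()].
#' @param schedule Optional [stimulus_schedule()]; defaults to the one
#'   attached to the experiment.
#' @return List with `corrected`, `efret`, `activity`, and `summary`
#'   (the [estimate_adaptation_time()] result, or NULL without events).
#' @export
analyze_fret_experiment <- function(exp, constants, schedule = NULL) {
  schedule <- schedule %||% attr(exp, "schedule")
  if (is.null(schedule)) stop("a stimulus schedule is required", call. = FALSE)
  corrected <- correct_fret_channels(exp, constants = constants)
  ef <- compute_efret(corrected, constants)
  act <- normalize_activity(ef, schedule)
  summary <- NULL
  ev <- schedule$events
  if (!is.null(ev) && any(ev$kind == "add")) {
    t_stim <- ev$time_s[ev$kind == "add"][1L]
    # baseline window: after any leading saturating window, before the stimulus
    w <- schedule$saturating_windows
    t_min <- if (!is.null(w)) max(c(0, w$t_end[w$t_end <= t_stim])) else 0
    sub <- act[act$time_s >= t_min, , drop = FALSE]
    summary <- estimate_adaptation_time(sub, t_stim)
  }
  list(corrected = corrected, efret = ef, activity = act, summary = summary)
}
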