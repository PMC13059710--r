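#' Step-stimulus kinase activity model
#'
#' Phenomenological model of CheA kinase activity under step stimuli:
#' activity sits at a baseline, jumps to a peak when a repellent is added,
#' relaxes back to baseline with an adaptation time constant (the pathway's
#' methylation-independent adaptation, about one minute), undershoots below
#' baseline when the stimulus is removed, and recovers.
#'
#' @param baseline_activity Pre-stimulus kinase activity (fraction in
#'   \[0, 1\]).
#' @param peak_activity Activity reached immediately on stimulus addition.
#' @param adaptation_tau_s Exponential adaptation time constant (s).
#' @param removal_undershoot Depth of the post-removal undershoot below
#'   baseline (fraction).
#' @param recovery_tau_s Recovery time constant after removal (s).
#' @param e_min,e_max FRET-efficiency bounds mapped to activity 0 and 1.
#' @return Object of class `kinase_step_model`.
#' @export
kinase_step_model <- function(baseline_activity = 0.35, peak_activity = 0.9,
                              adaptation_tau_s = 60, removal_undershoot = 0.15,
                              recovery_tau_s = 30, e_min = 0.05, e_max = 0.30) {
  if (baseline_activity < 0 || baseline_activity > 1 ||
      peak_activity < 0 || peak_activity > 1)
    stop("activities must lie in [0, 1]", call. = FALSE)
  if (!(e_min >= 0 && e_min < e_max && e_max <= 1))
    stop("need 0 <= e_min < e_max <= 1", call. = FALSE)
  if (adaptation_tau_s <= 0 || recovery_tau_s <= 0)
    stop("time constants must be > 0", call. = FALSE)
  structure(list(baseline_activity = baseline_activity,
                 peak_activity = peak_activity,
                 adaptation_tau_s = adaptation_tau_s,
                 removal_undershoot = removal_undershoot,
                 recovery_tau_s = recovery_tau_s,
                 e_min = e_min, e_max = e_max),
            class = "kinase_step_model")
}

#' Bi-exponential photobleaching model
#'
#' Normalized fluorophore bleaching decay
#' `f(t) = amp1 * exp(-t / tau1) + (1 - amp1) * exp(-t / tau2)`, so
#' `f(0) = 1`. Infinite time constants give no bleaching.
#'
#' @param amp1 Amplitude of the first component (fraction in \[0, 1\]).
#' @param tau1,tau2 Decay time constants (s), > 0 (may be `Inf`).
#' @return Object of class `bleach_model`.
#' @export
bleach_model <- function(amp1 = 0.3, tau1 = 80, tau2 = 1000) {
  if (amp1 < 0 || amp1 > 1) stop("amp1 must lie in [0, 1]", call. = FALSE)
  if (tau1 <= 0 || tau2 <= 0) stop("time constants must be > 0", call. = FALSE)
  structure(list(amp1 = amp1, amp2 = 1 - amp1, tau1 = tau1, tau2 = tau2),
            class = "bleach_model")
}

#' Evaluate a bleaching decay
#'
#' @param model A [bleach_model()].
#' @param t Times (s), >= 0.
#' @return Decay values in (0, 1\].
#' @export
bleach_decay <- function(model, t) {
  stopifnot(inherits(model, "bleach_model"))
  model$amp1 * exp(-t / model$tau1) + model$amp2 * exp(-t / model$tau2)
}

#' Optical constants of the E-FRET equation
#'
#' The three-cube (E-FRET) method needs the bleed-through constants `a`
#' (acceptor emission excited directly in the donor cube, measured on
#' acceptor-only cells as IDA/IAA) and `d` (donor bleed-through into the
#' FRET channel, measured on donor-only cells as IDA/IDD), plus the gauge
#' factor `G` relating sensitized emission lost to donor emission recovered
#' on acceptor photobleaching.
#'
#' @param a,d Bleed-through constants, >= 0.
#' @param G Gauge factor; must exceed `d` or the E-FRET denominator can
#'   vanish for valid signals.
#' @return Object of class `efret_constants`.
#' @export
efret_constants <- function(a = 0.08, d = 0.12, G = 1.8) {
  if (a < 0 || d < 0) stop("a and d must be >= 0", call. = FALSE)
  if (G <= d) stop("G must be greater than d", call. = FALSE)
  structure(list(a = a, d = d, G = G), class = "efret_constants")
}

#' Stimulus schedule for a FRET experiment
#'
#' @param events Data frame with columns `time_s`, `kind` (`"add"` or
#'   `"remove"`), and optionally `ligand`, `concentration`.
#' @param saturating_windows Data frame with columns `t_start`, `t_end`,
#'   `extreme` (`"min"` or `"max"`): windows in which a saturating stimulus
#'   drives kinase activity (hence FRET) to its extreme; used for per-cell
#'   min-max normalization.
#' @param duration_s Recording duration (s); all times must fall inside it.
#' @return Object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(events = NULL, saturating_windows = NULL,
                              duration_s) {
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("time_s", "kind") %in% names(events)))
    if (!all(events$kind %in% c("add", "remove")))
      stop("event kind must be 'add' or 'remove'", call. = FALSE)
    if (any(events$time_s < 0 | events$time_s > duration_s))
      stop("event times must lie within the recording", call. = FALSE)
    events <- events[order(events$time_s), , drop = FALSE]
  }
  if (!is.null(saturating_windows)) {
    w <- as.data.frame(saturating_windows)
    stopifnot(all(c("t_start", "t_end", "extreme") %in% names(w)))
    if (!all(w$extreme %in% c("min", "max")))
      stop("window extreme must be 'min' or 'max'", call. = FALSE)
    if (any(w$t_start < 0 | w$t_end > duration_s | w$t_end <= w$t_start))
      stop("saturating windows must lie within the recording", call. = FALSE)
    w <- w[order(w$t_start), , drop = FALSE]
    if (nrow(w) > 1L && any(w$t_start[-1L] < w$t_end[-nrow(w)]))
      stop("saturating windows must not overlap", call. = FALSE)
    saturating_windows <- w
  }
  structure(list(events = events, saturating_windows = saturating_windows,
                 duration_s = duration_s),
            class = "stimulus_schedule")
}

#' Default demonstration schedule
#'
#' A 600-s protocol: a saturating kinase-ON window early (5-20 s), a step
#' stimulus added at 60 s and removed at 180 s, and a saturating kinase-OFF
#' window late (560-575 s). The two saturating windows provide the per-cell
#' min and max FRET levels used for normalization.
#'
#' @param duration_s Recording duration (s). Default 600.
#' @return A [stimulus_schedule()].
#' @export
default_fret_schedule <- function(duration_s = 600) {
  stimulus_schedule(
    events = data.frame(time_s = c(60, 180), kind = c("add", "remove"),
                        ligand = "H2O2", concentration = "1 mM"),
    saturating_windows = data.frame(t_start = c(5, duration_s - 40),
                                    t_end = c(20, duration_s - 25),
                                    extreme = c("max", "min")),
    duration_s = duration_s)
}

#' Ground-truth kinase activity trajectory
#'
#' Evaluates the step-stimulus kinase model on a time grid under a stimulus
#' schedule: each `add` event resets activity to the peak with exponential
#' adaptation back to baseline; each `remove` event drops it below baseline
#' by the undershoot depth with exponential recovery. Saturating windows
#' override activity to 0 (`min`) or 1 (`max`). The result is clipped to
#' \[0, 1\].
#'
#' @param kinase A [kinase_step_model()].
#' @param schedule A [stimulus_schedule()].
#' @param t Time grid (s).
#' @return Numeric activity vector on `t`.
#' @export
activity_profile <- function(kinase, schedule, t) {
  stopifnot(inherits(kinase, "kinase_step_model"),
            inherits(schedule, "stimulus_schedule"))
  base <- kinase$baseline_activity
  a <- rep(base, length(t))
  ev <- schedule$events
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      t0 <- ev$time_s[i]
      idx <- t >= t0
      if (ev$kind[i] == "add") {
        a[idx] <- base + (kinase$peak_activity - base) *
          exp(-(t[idx] - t0) / kinase$adaptation_tau_s)
      } else {
        a[idx] <- base - kinase$removal_undershoot *
          exp(-(t[idx] - t0) / kinase$recovery_tau_s)
      }
    }
  }
  w <- schedule$saturating_windows
  if (!is.null(w)) {
    for (i in seq_len(nrow(w))) {
      idx <- t >= w$t_start[i] & t < w$t_end[i]
      a[idx] <- if (w$extreme[i] == "max") 1 else 0
    }
  }
  pmin(pmax(a, 0), 1)
}

#' Simulate a three-channel single-cell FRET recording
#'
#' Forward model of the three-cube FRET measurement. The ground-truth
#' efficiency is `E(t) = e_min + (e_max - e_min) * activity(t)`; channel
#' intensities are
#' \describe{
#'   \item{IDD}{`i0_donor * (1 - E) * bleach_donor(t)` - donor emission under
#'     donor excitation, quenched by transfer;}
#'   \item{IAA}{`i0_acceptor * bleach_acceptor(t)` - acceptor emission under
#'     acceptor excitation;}
#'   \item{IDA}{`G * E * i0_donor * bleach_donor(t) + a * IAA + d * IDD` -
#'     sensitized emission plus the two bleed-through terms.}
#' }
#' Multiplicative Gaussian noise (shot-noise stand-in) is applied last. By
#' construction, [compute_efret()] applied to the noiseless channels returns
#' `E(t)` exactly.
#'
#' @param kinase A [kinase_step_model()].
#' @param bleach_donor,bleach_acceptor [bleach_model()]s for the two
#'   fluorophores.
#' @param constants An [efret_constants()].
#' @param schedule A [stimulus_schedule()]; its `duration_s` sets the
#'   recording length.
#' @param dt_s Frame interval (s). Default 0.05 (50-ms exposures).
#' @param i0_donor,i0_acceptor Unbleached channel amplitudes (counts).
#' @param shot_noise_sd Relative SD of the multiplicative noise. Default
#'   0.01; 0 gives noiseless channels.
#' @param seed Optional integer seed.
#' @param cell_id Label stored with the experiment.
#' @return A `fret_experiment` data frame (`time_s`, `IDD`, `IDA`, `IAA`)
#'   with attributes `schedule`, `cell_id`, `constants`, and `truth`
#'   (list with ground-truth `efficiency` and `activity`).
#' @export
simulate_fret_experiment <- function(kinase = kinase_step_model(),
                                     bleach_donor = bleach_model(0.3, 80, 1000),
                                     bleach_acceptor = bleach_model(0.25, 120, 1500),
                                     constants = efret_constants(),
                                     schedule = default_fret_schedule(),
                                     dt_s = 0.05,
                                     i0_donor = 1000, i0_acceptor = 1000,
                                     shot_noise_sd = 0.01, seed = NULL,
                                     cell_id = "cell_1") {
  stopifnot(inherits(kinase, "kinase_step_model"),
            inherits(constants, "efret_constants"),
            inherits(schedule, "stimulus_schedule"))
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  with_local_seed(seed, {
    t <- seq(0, schedule$duration_s - dt_s, by = dt_s)
    act <- activity_profile(kinase, schedule, t)
    E <- kinase$e_min + (kinase$e_max - kinase$e_min) * act
    bD <- bleach_decay(bleach_donor, t)
    bA <- bleach_decay(bleach_acceptor, t)
    IDD <- i0_donor * (1 - E) * bD
    IAA <- i0_acceptor * bA
    IDA <- constants$G * E * i0_donor * bD + constants$a * IAA + constants$d * IDD
    if (shot_noise_sd > 0) {
      n <- length(t)
      IDD <- pmax(IDD * (1 + stats::rnorm(n, 0, shot_noise_sd)), 0)
      IDA <- pmax(IDA * (1 + stats::rnorm(n, 0, shot_noise_sd)), 0)
      IAA <- pmax(IAA * (1 + stats::rnorm(n, 0, shot_noise_sd)), 0)
    }
    out <- data.frame(time_s = t, IDD = IDD, IDA = IDA, IAA = IAA)
    class(out) <- c("fret_experiment", "data.frame")
    attr(out, "schedule") <- schedule
    attr(out, "cell_id") <- cell_id
    attr(out, "constants") <- constants
    attr(out, "truth") <- list(efficiency = E, activity = act)
    trivial <- function(b) (is.infinite(b$tau1) || b$amp1 == 0) &&
      (is.infinite(b$tau2) || b$amp2 == 0)
    attr(out, "corrected") <- trivial(bleach_donor) && trivial(bleach_acceptor)
    out
  })
}
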