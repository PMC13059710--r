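#' Render a synthetic defocused diffraction-ring image
#'
#' Generates a radially symmetric annulus on a square pixel grid: intensity
#' `amplitude * exp(-(r - diameter/2)^2 / (2 * psf_width^2))` about the
#' image center (with optional sub-pixel offset), plus Gaussian background
#' noise. The ring diameter follows the linear calibration at the requested
#' height.
#'
#' @param z_um Cell height (um) within the calibration range.
#' @param calibration A [ring_calibration()].
#' @param image_size_px Side length of the square image (px). Default 96.
#' @param psf_width_px Gaussian radial width of the ring (px). Default 1.5.
#' @param amplitude Peak ring intensity (counts). Default 255.
#' @param background_sd Gaussian background noise SD (counts). Default 8.
#' @param center_offset_px Length-2 sub-pixel offset of the ring center from
#'   the image center (px). Default `c(0, 0)`.
#' @param seed Optional integer seed.
#' @return A numeric `image_size_px` x `image_size_px` matrix with
#'   attributes `z_um`, `diameter_px`, `center_px`.
#' @export
render_ring_image <- function(z_um, calibration = ring_calibration(),
                              image_size_px = 96, psf_width_px = 1.5,
                              amplitude = 255, background_sd = 8,
                              center_offset_px = c(0, 0), seed = NULL) {
  stopifnot(inherits(calibration, "ring_calibration"))
  zr <- calibration$z_range_um
  if (z_um < zr[1L] || z_um > zr[2L])
    stop(sprintf("z must lie within the calibrated range [%g, %g] um",
                 zr[1L], zr[2L]), call. = FALSE)
  diameter <- calibration$d0_px + calibration$slope_px_per_um * z_um
  if (diameter >= image_size_px)
    stop(sprintf("ring diameter (%.1f px) does not fit inside a %d px image",
                 diameter, image_size_px), call. = FALSE)
  with_local_seed(seed, {
    ctr <- (image_size_px + 1) / 2 + center_offset_px
    xs <- seq_len(image_size_px)
    dx2 <- (xs - ctr[1L])^2
    dy2 <- (xs - ctr[2L])^2
    r <- sqrt(outer(dx2, dy2, "+"))
    img <- amplitude * exp(-(r - diameter / 2)^2 / (2 * psf_width_px^2))
    if (background_sd > 0)
      img <- img + matrix(stats::rnorm(image_size_px^2, 0, background_sd),
                          image_size_px, image_size_px)
    attr(img, "z_um") <- z_um
    attr(img, "diameter_px") <- diameter
    attr(img, "center_px") <- ctr
    img
  })
}

#' Estimate a diffraction-ring diameter from an image
#'
#' Refines the ring center by intensity centroid (after subtracting the
#' median background), bins pixel intensities into 0.25-px annuli with
#' linear interpolation between adjacent bins, and reads the ring radius
#' off the radial profile peak with quadratic sub-bin interpolation. The
#' quality score is the profile-peak prominence over the background noise
#' SD estimated from the image border.
#'
#' @param image Numeric matrix (one ring per image).
#' @param center_guess Optional length-2 center (px); default: intensity
#'   centroid.
#' @param bin_width_px Radial bin width (px). Default 0.25.
#' @param min_quality Detection threshold on the quality score. Default 5.
#' @return List with `diameter_px`, `radius_px`, `center_px`, `quality`,
#'   and `focused_spot` (TRUE when the profile peaks in the innermost
#'   bins, i.e. the cell is essentially in focus).
#' @export
estimate_ring_diameter <- function(image, center_guess = NULL,
                                   bin_width_px = 0.25, min_quality = 5) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  bg <- stats::median(image)
  pos <- pmax(image - bg, 0)
  if (is.null(center_guess)) {
    tot <- sum(pos)
    if (tot <= 0) stop("detection failure: image carries no signal", call. = FALSE)
    xs <- seq_len(n)
    cx <- sum(rowSums(pos) * xs) / tot
    cy <- sum(colSums(pos) * xs) / tot
    center <- c(cx, cy)
  } else {
    center <- center_guess
  }
  xs <- seq_len(n)
  r <- sqrt(outer((xs - center[1L])^2, (xs - center[2L])^2, "+"))
  # linear-interpolation binning: each pixel splits between the two
  # nearest bin centers
  b <- r / bin_width_px
  b0 <- floor(b)
  w1 <- b - b0
  n_bins <- max(b0) + 2L
  i0 <- b0 + 1L
  v <- as.vector(image)
  num <- tabulate_weighted(i0, v * (1 - w1), n_bins) +
    tabulate_weighted(i0 + 1L, v * w1, n_bins)
  den <- tabulate_weighted(i0, 1 - w1, n_bins) +
    tabulate_weighted(i0 + 1L, w1, n_bins)
  keep <- den > 0
  profile <- num[keep] / den[keep]
  radii <- (which(keep) - 1L) * bin_width_px
  # ignore bins beyond the inscribed circle, where annuli are clipped
  ok <- radii <= (n / 2 - 1)
  profile <- profile[ok]
  radii <- radii[ok]
  ipk <- which.max(profile)
  # background noise from the image border
  border <- c(image[1:2, ], image[(n - 1):n, ], image[, 1:2], image[, (n - 1):n])
  noise_sd <- stats::sd(border)
  prominence <- profile[ipk] - stats::median(profile)
  quality <- if (noise_sd > 0) prominence / noise_sd else Inf
  if (quality < min_quality)
    stop(sprintf("detection failure: no prominent ring (quality %.2f < %.2f)",
                 quality, min_quality), call. = FALSE)
  focused_spot <- radii[ipk] <= 2 * bin_width_px
  radius <- radii[ipk]
  if (ipk > 1L && ipk < length(profile)) {
    y0 <- profile[ipk - 1L]; y1 <- profile[ipk]; y2 <- profile[ipk + 1L]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) radius <- radius + 0.5 * (y0 - y2) / denom * bin_width_px
  }
  list(diameter_px = 2 * radius, radius_px = radius, center_px = center,
       quality = quality, focused_spot = focused_spot)
}

# weighted tabulate: sums w over integer bins 1..n_bins
tabulate_weighted <- function(bin, w, n_bins) {
  out <- numeric(n_bins)
  ok <- bin >= 1L & bin <= n_bins
  agg <- rowsum(w[ok], bin[ok])
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Summarize and compare vertical cell distributions across conditions
#'
#' Per-condition descriptive statistics of cell heights plus a paired
#' Student's t-test of each condition against the control, pairing
#' replicate means (the replicate plate is the pairing unit). The bottom-
#' layer occupancy (fraction of cells within `bottom_um` of the surface)
#' is reported as the effect summary.
#'
#' @param observations Data frame with columns `z_um`, `condition`,
#'   `replicate` (see [read_ring_observations()]); a `diameter_px` column
#'   plus `calibration` may be given instead of `z_um`.
#' @param control Name of the control condition.
#' @param calibration Optional [ring_calibration()] used to map
#'   `diameter_px` to `z_um` when heights are absent.
#' @param bottom_um Bottom-layer thickness for the occupancy summary (um).
#'   Default 20.
#' @return A `colony_summary` list: `per_condition` data frame (n, mean,
#'   median, quartiles, bottom-layer fraction) and `tests` data frame
#'   (paired t statistic, df, p-value per non-control condition).
#' @export
summarize_colony <- function(observations, control, calibration = NULL,
                             bottom_um = 20) {
  obs <- as.data.frame(observations)
  if (!"z_um" %in% names(obs)) {
    if (is.null(calibration) || !"diameter_px" %in% names(obs))
      stop("observations need a z_um column, or diameter_px plus a calibration",
           call. = FALSE)
    obs$z_um <- as.numeric(diameter_to_z(obs$diameter_px, calibration))
  }
  stopifnot(all(c("condition", "replicate") %in% names(obs)))
  if (!control %in% obs$condition)
    stop(sprintf("control condition '%s' not present", control), call. = FALSE)
  conds <- unique(obs$condition)
  per <- do.call(rbind, lapply(conds, function(cc) {
    z <- obs$z_um[obs$condition == cc]
    data.frame(condition = cc, n = length(z), mean_z_um = mean(z),
               median_z_um = stats::median(z),
               q25_z_um = unname(stats::quantile(z, 0.25)),
               q75_z_um = unname(stats::quantile(z, 0.75)),
               frac_bottom = mean(z <= bottom_um),
               stringsAsFactors = FALSE)
  }))
  rep_means <- function(cc) {
    z <- obs[obs$condition == cc, , drop = FALSE]
    tapply(z$z_um, z$replicate, mean)
  }
  ctrl_means <- rep_means(control)
  tests <- do.call(rbind, lapply(setdiff(conds, control), function(cc) {
    m <- rep_means(cc)
    shared <- intersect(names(m), names(ctrl_means))
    if (length(shared) < 2L)
      stop(sprintf("pairing error: conditions '%s' and '%s' share fewer than 2 replicates",
                   cc, control), call. = FALSE)
    if (length(shared) < length(m) || length(shared) < length(ctrl_means))
      warning(sprintf("dropping unpaired replicates when comparing '%s' to '%s'",
                      cc, control), call. = FALSE)
    d <- m[shared] - ctrl_means[shared]
    if (all(d == 0)) {       # identical paired replicates: no effect, no spread
      stat <- 0; dof <- length(shared) - 1L; pv <- 1
    } else {
      tt <- stats::t.test(m[shared], ctrl_means[shared], paired = TRUE)
      stat <- unname(tt$statistic); dof <- unname(tt$parameter); pv <- tt$p.value
    }
    data.frame(condition = cc, control = control,
               statistic = stat, df = dof,
               p_value = pv, n_pairs = length(shared),
               stringsAsFactors = FALSE)
  }))
  out <- list(per_condition = per, tests = tests, control = control,
              bottom_um = bottom_um)
  class(out) <- "colony_summary"
  out
}

#' @export
print.colony_summary <- function(x, ...) {
  cat("Colony vertical-distribution summary\n")
  print(x$per_condition, row.names = FALSE)
  if (!is.null(x$tests) && nrow(x$tests) > 0L) {
    cat(sprintf("\nPaired t-tests of replicate mean z vs control '%s':\n", x$control))
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
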