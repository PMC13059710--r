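#' Diffraction-ring diameter-to-height calibration
#'
#' In defocused epifluorescence imaging a cell above the focal plane shows
#' an out-of-focus diffraction ring whose diameter grows with its height.
#' The package models the calibration as strictly linear,
#' `diameter = d0 + slope * z`, over the colony height range.
#'
#' @param d0_px In-focus ring diameter (px), >= 0.
#' @param slope_px_per_um Diameter increase per micron of height (px/um),
#'   > 0 so that the map is strictly monotonic.
#' @param z_max_um Upper end of the calibrated height range (um); default
#'   150, a typical swarm-colony height.
#' @param noise_sd_px Diameter measurement noise SD (px) used by the
#'   observation simulator. Default 0.1.
#' @return Object of class `ring_calibration`.
#' @export
ring_calibration <- function(d0_px = 6, slope_px_per_um = 0.5,
                             z_max_um = 150, noise_sd_px = 0.1) {
  if (d0_px < 0) stop("d0_px must be >= 0", call. = FALSE)
  if (slope_px_per_um <= 0) stop("slope_px_per_um must be > 0", call. = FALSE)
  if (z_max_um <= 0) stop("z_max_um must be > 0", call. = FALSE)
  if (noise_sd_px < 0) stop("noise_sd_px must be >= 0", call. = FALSE)
  structure(list(d0_px = d0_px, slope_px_per_um = slope_px_per_um,
                 z_range_um = c(0, z_max_um), noise_sd_px = noise_sd_px),
            class = "ring_calibration")
}

#' Simulate ring-diameter observations at known heights
#'
#' @param calibration A [ring_calibration()].
#' @param z_um Heights (um), all within the calibration range.
#' @param seed Optional integer seed.
#' @param condition,replicate Labels stored with the observations.
#' @return A `ring_observations` data frame with columns `z_true_um`,
#'   `diameter_px`, `condition`, `replicate`.
#' @export
simulate_ring_observations <- function(calibration, z_um, seed = NULL,
                                       condition = "synthetic", replicate = 1L) {
  stopifnot(inherits(calibration, "ring_calibration"))
  zr <- calibration$z_range_um
  if (any(z_um < zr[1L] | z_um > zr[2L]))
    stop(sprintf("z values must lie within the calibrated range [%g, %g] um",
                 zr[1L], zr[2L]), call. = FALSE)
  with_local_seed(seed, {
    d <- calibration$d0_px + calibration$slope_px_per_um * z_um +
      stats::rnorm(length(z_um), 0, calibration$noise_sd_px)
    out <- data.frame(z_true_um = z_um, diameter_px = d,
                      condition = condition, replicate = replicate,
                      stringsAsFactors = FALSE)
    class(out) <- c("ring_observations", "data.frame")
    out
  })
}

#' Invert the ring calibration: diameter to height
#'
#' `z = (diameter - d0) / slope`, clamped to the calibrated height range.
#'
#' @param diameter_px Ring diameters (px).
#' @param calibration A [ring_calibration()].
#' @return Heights (um) with attribute `out_of_range` (logical vector
#'   marking clamped values).
#' @export
diameter_to_z <- function(diameter_px, calibration) {
  stopifnot(inherits(calibration, "ring_calibration"))
  z <- (diameter_px - calibration$d0_px) / calibration$slope_px_per_um
  zr <- calibration$z_range_um
  oob <- z < zr[1L] | z > zr[2L]
  z <- pmin(pmax(z, zr[1L]), zr[2L])
  attr(z, "out_of_range") <- oob
  z
}

#' Preset vertical distributions of cells inside a swarm colony
#'
#' Ground-truth height distributions used to emulate the two colony
#' phenotypes: wild-type cells on a sublethal aminoglycoside crowd into the
#' upper colony (truncated normal centered high), while the
#' receptor-deletion strain spreads uniformly over the full height.
#'
#' @param name `"wt_kanamycin"` (truncated normal, mean 100 um, SD 25 um,
#'   truncated to \[0, 150\]) or `"aer_null"` (uniform over \[0, 150\]).
#' @param n Number of cells.
#' @param z_max_um Colony height (um). Default 150.
#' @param seed Optional integer seed.
#' @return Numeric vector of heights (um).
#' @export
preset_colony_z <- function(name = c("wt_kanamycin", "aer_null"), n,
                            z_max_um = 150, seed = NULL) {
  name <- match.arg(name)
  with_local_seed(seed, {
    if (name == "aer_null") {
      stats::runif(n, 0, z_max_um)
    } else {
      mu <- 2 / 3 * z_max_um
      sd <- z_max_um / 6
      # inverse-CDF sampling of the truncated normal
      plo <- stats::pnorm(0, mu, sd)
      phi <- stats::pnorm(z_max_um, mu, sd)
      stats::qnorm(stats::runif(n, plo, phi), mu, sd)
    }
  })
}
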