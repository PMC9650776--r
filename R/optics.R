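#' Optical configuration of the low-dispersion grating setup
#'
#' Geometry of a blazed transmission grating placed a few millimetres in
#' front of the camera chip, plus the imaging parameters needed to express
#' everything in sample-plane nanometres. Defaults describe a 70 lines/mm
#' grating at 6.9 mm from the chip; magnification and pixel size are chosen
#' such that the 1st order of a 692 nm emitter lands 3077 nm (sample plane)
#' from the 0th order and the dispersion is ~27 nm of wavelength per camera
#' pixel.
#'
#' @param grating_pitch Grating line density (lines per mm), > 0.
#' @param grating_to_chip_mm Distance z from the dispersing surface to the
#'   chip (mm), > 0.
#' @param magnification Total magnification M of the imaging path, > 0.
#' @param pixel_size_nm Sample-plane pixel pitch (nm), > 0.
#' @param first_order_efficiency Fraction of detected photons diffracted into
#'   the 1st order (a blazed grating puts roughly half the light in each of
#'   the 0th and 1st orders), in (0, 1).
#' @param dispersion_axis_deg Angle of the dispersion direction in the image
#'   plane (degrees, counter-clockwise from +x).
#' @param psf_sigma_nm Diffraction-limited point-spread-function standard
#'   deviation in sample-plane nm, > 0.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(grating_pitch = 70, grating_to_chip_mm = 6.9,
                           magnification = 108.75, pixel_size_nm = 126.4,
                           first_order_efficiency = 0.5,
                           dispersion_axis_deg = 0, psf_sigma_nm = 150) {
  if (grating_pitch <= 0) stop("grating_pitch must be positive")
  if (grating_to_chip_mm <= 0) stop("grating_to_chip_mm must be positive")
  if (magnification <= 0) stop("magnification must be positive")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (first_order_efficiency <= 0 || first_order_efficiency >= 1)
    stop("first_order_efficiency must be in (0, 1)")
  if (psf_sigma_nm <= 0) stop("psf_sigma_nm must be positive")
  structure(list(grating_pitch = grating_pitch,
                 grating_to_chip_mm = grating_to_chip_mm,
                 magnification = magnification,
                 pixel_size_nm = pixel_size_nm,
                 first_order_efficiency = first_order_efficiency,
                 dispersion_axis_deg = dispersion_axis_deg,
                 psf_sigma_nm = psf_sigma_nm),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0("<optical_config> %g lines/mm at z = %g mm, M = %g, ",
                     "px = %g nm, eta1 = %g, axis %g deg, PSF sigma %g nm\n"),
              x$grating_pitch, x$grating_to_chip_mm, x$magnification,
              x$pixel_size_nm, x$first_order_efficiency,
              x$dispersion_axis_deg, x$psf_sigma_nm))
  invisible(x)
}

#' Geometric 0th-to-1st-order displacement
#'
#' First-order diffraction displacement of wavelength `lambda` on the chip,
#' `z * tan(asin(lambda * g))`, converted to sample-plane nm by dividing by
#' the magnification. Strictly increasing in wavelength.
#'
#' @param wavelength_nm Emission wavelength (nm).
#' @param config An [optical_config()].
#' @return Sample-plane displacement (nm).
#' @export
diffraction_displacement <- function(wavelength_nm, config) {
  lg <- wavelength_nm * config$grating_pitch * 1e-6
  if (any(lg >= 1))
    stop("lambda * g >= 1: first diffraction order is evanescent")
  if (any(lg < 0)) stop("wavelength must be non-negative")
  z_nm <- config$grating_to_chip_mm * 1e6
  z_nm * tan(asin(lg)) / config$magnification
}

#' Local spectral dispersion of the geometric model
#'
#' Inverse derivative of [diffraction_displacement()] with respect to
#' wavelength: nm of wavelength per nm of sample-plane distance,
#' `M * (1 - (lambda g)^2)^(3/2) / (z g)`. In the small-angle limit this is
#' `M / (z g)`. Note the geometric value at 692 nm (~0.224 for the default
#' configuration) sits ~5% above a typical measured calibration (~0.21): the
#' effective optical path of a real system (grating substrate, exact chip
#' plane) is not captured, so a measured [calibrate_dispersion()] result
#' should be preferred for data analysis.
#'
#' @inheritParams diffraction_displacement
#' @return Spectral dispersion (nm wavelength / nm distance).
#' @export
local_dispersion <- function(wavelength_nm, config) {
  lg <- wavelength_nm * config$grating_pitch * 1e-6
  if (any(lg >= 1))
    stop("lambda * g >= 1: first diffraction order is evanescent")
  z_nm <- config$grating_to_chip_mm * 1e6
  g_per_nm <- config$grating_pitch * 1e-6
  config$magnification * (1 - lg^2)^1.5 / (z_nm * g_per_nm)
}

#' Dispersion calibration
#'
#' Linear map between the 0th-to-1st-order distance `d` and the mean emission
#' wavelength: `lambda(d) = lambda0 + sd * (d - d0)`. Over a 650-720 nm
#' working band the curvature of the grating geometry is below 0.5%, so a
#' linear calibration anchored at a reference point is adequate.
#'
#' @param sd_nm_per_nm Spectral dispersion: nm of wavelength per nm of
#'   sample-plane distance, > 0.
#' @param anchor_distance_nm Reference distance d0 (nm), > 0.
#' @param anchor_wavelength_nm Reference mean wavelength lambda0 (nm).
#' @param axis_deg Calibrated dispersion-axis angle (degrees).
#' @return An object of class `dispersion_calibration`.
#' @export
dispersion_calibration <- function(sd_nm_per_nm, anchor_distance_nm,
                                   anchor_wavelength_nm, axis_deg = 0) {
  if (sd_nm_per_nm <= 0) stop("spectral dispersion must be positive")
  if (anchor_distance_nm <= 0) stop("anchor distance must be positive")
  structure(list(sd_nm_per_nm = sd_nm_per_nm,
                 anchor_distance_nm = anchor_distance_nm,
                 anchor_wavelength_nm = anchor_wavelength_nm,
                 axis_deg = axis_deg),
            class = "dispersion_calibration")
}

#' @export
print.dispersion_calibration <- function(x, ...) {
  cat(sprintf(paste0("<dispersion_calibration> sd = %.4f nm/nm, anchor ",
                     "(%.0f nm, %.1f nm), axis %g deg\n"),
              x$sd_nm_per_nm, x$anchor_distance_nm, x$anchor_wavelength_nm,
              x$axis_deg))
  invisible(x)
}

#' Calibrate the spectral dispersion from measured (distance, wavelength) pairs
#'
#' Least-squares slope of mean emission wavelength against median
#' 0th-to-1st-order distance, over two or more reference fluorophores. With
#' exactly two points this reduces to the two-point slope. The first point
#' serves as the calibration anchor.
#'
#' @param points A data frame (or 2-column matrix) with columns
#'   `distance_nm` and `wavelength_nm`; one row per reference fluorophore,
#'   using the population median distance and the transmission-corrected
#'   weighted mean emission wavelength.
#' @param axis_deg Dispersion-axis angle (degrees) determined from pairing
#'   statistics, constant across wavelengths.
#' @return A [dispersion_calibration()].
#' @export
calibrate_dispersion <- function(points, axis_deg = 0) {
  points <- as.data.frame(points)
  if (is.null(points$distance_nm) || is.null(points$wavelength_nm)) {
    if (ncol(points) >= 2) names(points)[1:2] <- c("distance_nm", "wavelength_nm")
    else stop("points must have columns distance_nm and wavelength_nm")
  }
  if (nrow(points) < 2)
    stop("calibration needs at least two reference points")
  if (diff(range(points$distance_nm)) <= 0)
    stop("calibration points must have distinct distances")
  fit <- stats::lm(wavelength_nm ~ distance_nm, data = points)
  sd_hat <- unname(stats::coef(fit)["distance_nm"])
  if (sd_hat <= 0)
    stop("fitted spectral dispersion is non-positive; check point ordering")
  dispersion_calibration(sd_hat, points$distance_nm[1],
                         points$wavelength_nm[1], axis_deg = axis_deg)
}

#' Convert a 0th-to-1st-order distance to a mean emission wavelength
#'
#' @param distance_nm Distance(s) (nm), > 0.
#' @param cal A [dispersion_calibration()].
#' @return Mean emission wavelength(s) (nm).
#' @export
distance_to_wavelength <- function(distance_nm, cal) {
  if (any(distance_nm <= 0)) stop("distance must be positive")
  cal$anchor_wavelength_nm +
    cal$sd_nm_per_nm * (distance_nm - cal$anchor_distance_nm)
}

#' Inverse of [distance_to_wavelength()]
#'
#' @param wavelength_nm Mean emission wavelength(s) (nm).
#' @param cal A [dispersion_calibration()].
#' @return 0th-to-1st-order distance(s) (nm).
#' @export
wavelength_to_distance <- function(wavelength_nm, cal) {
  cal$anchor_distance_nm +
    (wavelength_nm - cal$anchor_wavelength_nm) / cal$sd_nm_per_nm
}

#' Spectral separation corresponding to a distance difference
#'
#' @param delta_distance_nm Difference of 0th-to-1st-order distances (nm).
#' @param cal A [dispersion_calibration()].
#' @return Spectral separation `sd * delta_d` (nm).
#' @export
wavelength_separation <- function(delta_distance_nm, cal) {
  cal$sd_nm_per_nm * delta_distance_nm
}

#' Build a calibration from the geometric grating model
#'
#' Convenience for simulations without a measured calibration: anchors the
#' linear map at `anchor_wavelength_nm` using [diffraction_displacement()]
#' and [local_dispersion()].
#'
#' @param config An [optical_config()].
#' @param anchor_wavelength_nm Wavelength at which to anchor (nm).
#' @return A [dispersion_calibration()].
#' @export
calibration_from_config <- function(config, anchor_wavelength_nm = 692) {
  dispersion_calibration(
    sd_nm_per_nm = local_dispersion(anchor_wavelength_nm, config),
    anchor_distance_nm = diffraction_displacement(anchor_wavelength_nm, config),
    anchor_wavelength_nm = anchor_wavelength_nm,
    axis_deg = config$dispersion_axis_deg)
}
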