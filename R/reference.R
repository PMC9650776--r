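#' Reference fluorophore table for the default instrument
#'
#' Published working values for four red-emitting fluorophores imaged on the
#' default low-dispersion configuration: the transmission-corrected weighted
#' mean and peak emission wavelengths, the median 0th-to-1st-order distance
#' of the fitted population, the Gaussian width of that population, and the
#' quantum yield where known. The mean-wavelength order (685, 692, 693,
#' 701 nm) matches the distance order (3014, 3077, 3090, 3128 nm), which is
#' the core premise of distance-based spectral classification.
#'
#' @return A data frame with columns `dye`, `lambda_mean_nm`,
#'   `lambda_peak_nm`, `d_nm`, `sigma_d_nm`, `quantum_yield`.
#' @export
reference_dyes <- function() {
  data.frame(
    dye = c("ATTO647N", "CF660", "ATTO655", "CF680"),
    lambda_mean_nm = c(685, 692, 693, 701),
    lambda_peak_nm = c(665, 686, 679, 698),
    d_nm = c(3014, 3077, 3090, 3128),
    sigma_d_nm = c(34, 56, 41, 62),
    quantum_yield = c(0.65, NA, 0.30, NA),
    stringsAsFactors = FALSE)
}

#' Reference smFRET states in (distance, width) space
#'
#' Working state centers for a green-donor / red-acceptor (ATTO550/ATTO647N
#' style) surface-immobilized DNA FRET sample on the default instrument: the
#' donor-only state and two FRET states (~15% and ~55% apparent efficiency,
#' from 23-bp and 15-bp label separations). Both the 0th-to-1st-order
#' distance d and the 1st-order width sigma increase with FRET efficiency.
#' The covariances and weights are package defaults for synthetic data (the
#' published values are the centers); the background state models sparse
#' nonsense linkages as a broad diffuse component.
#'
#' @param include_background Add the broad background state.
#' @return A list of [fret_state()] objects.
#' @export
reference_fret_states <- function(include_background = TRUE) {
  states <- list(
    fret_state("donor_only", mean = c(2620, 172),
               covariance = diag(c(35^2, 30^2)), weight = 0.4),
    fret_state("fret_low", mean = c(2653, 204),
               covariance = diag(c(35^2, 30^2)), weight = 0.3),
    fret_state("fret_high", mean = c(2781, 238),
               covariance = diag(c(35^2, 30^2)), weight = 0.27))
  if (include_background)
    states <- c(states, list(
      fret_state("background", mean = c(2700, 205),
                 covariance = diag(c(200^2, 120^2)), weight = 0.03)))
  w <- vapply(states, function(s) s$weight, numeric(1))
  for (i in seq_along(states)) states[[i]]$weight <- w[i] / sum(w)
  states
}

#' Default measured dispersion calibration
#'
#' Linear distance-to-wavelength map with the measured spectral dispersion of
#' the default instrument (~0.21 nm of wavelength per nm of distance,
#' equivalently ~27 nm per camera pixel), anchored at the CF660 population
#' (3077 nm, 692 nm). Preferred over the geometric
#' [calibration_from_config()] for analysis, since the geometric model does
#' not capture the effective optical path of the real system.
#'
#' @return A [dispersion_calibration()].
#' @export
default_calibration <- function() {
  dispersion_calibration(sd_nm_per_nm = 10.9 / 51,
                         anchor_distance_nm = 3077,
                         anchor_wavelength_nm = 692,
                         axis_deg = 0)
}

#' Synthetic stand-in emission spectrum for a reference dye
#'
#' Builds a skew-normal spectrum (see [synth_spectrum()]) whose
#' transmission-corrected weighted mean wavelength matches the reference
#' table. All dyes share the same shape (width 20 nm, skew 3, red tail) and
#' are shifted in wavelength; this is a synthetic stand-in for vendor
#' spectra, not a measured curve.
#'
#' @param dye One of the names in [reference_dyes()].
#' @param width_nm,skew Shape parameters shared by all dyes.
#' @return A corrected `emission_spectrum` with the dye's quantum yield
#'   (1 where unknown).
#' @export
dye_spectrum <- function(dye, width_nm = 20, skew = 3) {
  ref <- reference_dyes()
  i <- match(dye, ref$dye)
  if (is.na(i)) stop("unknown dye: ", dye)
  target <- ref$lambda_mean_nm[i]
  qy <- ref$quantum_yield[i]
  if (is.na(qy)) qy <- 1
  base <- synth_spectrum(peak_nm = target, width_nm = width_nm, skew = skew)
  shift <- target - weighted_mean_wavelength(base)
  emission_spectrum(base$wavelengths_nm + shift, base$intensities,
                    name = paste0(dye, " (synthetic)"), quantum_yield = qy,
                    corrected = TRUE)
}
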