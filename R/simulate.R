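#' A single blinking emitter
#'
#' @param x_nm,y_nm Sample-plane position (nm). The pixel at index (0, 0)
#'   spans `[0, pixel_size) x [0, pixel_size)` nm (half-open intervals).
#' @param spectrum A transmission-corrected [emission_spectrum()]; the
#'   simulator refuses uncorrected spectra because rendered photons must
#'   already reflect the detection-path response.
#' @param photons Expected detected photons per frame (before the grating
#'   splits them between the orders), > 0.
#' @param frames Inclusive `c(first, last)` frame range while the emitter is
#'   on; `Inf` means on for the whole acquisition.
#' @return An object of class `sim_emitter`.
#' @export
emitter <- function(x_nm, y_nm, spectrum, photons = 2000,
                    frames = c(1, Inf)) {
  stopifnot_spectrum(spectrum)
  if (photons <= 0) stop("photons must be positive")
  frames <- as.numeric(frames)
  if (length(frames) != 2 || frames[1] > frames[2] || frames[1] < 1)
    stop("frames must be an inclusive range c(first, last) with first >= 1")
  structure(list(x_nm = x_nm, y_nm = y_nm, spectrum = spectrum,
                 photons = photons, frames = frames),
            class = "sim_emitter")
}

#' Camera noise model
#'
#' Photon shot noise is Poisson on the expected pixel intensity (signal plus
#' uniform background); read noise is additive Gaussian. Photons are camera
#' counts at unit gain (EM gain / sCMOS conversion is out of scope).
#'
#' @param background_per_px Mean background photons per pixel, >= 0.
#' @param read_noise_e Gaussian read-noise standard deviation (electrons,
#'   i.e. photons at unit gain), >= 0.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_per_px = 10, read_noise_e = 1.5,
                        seed = NULL) {
  if (background_per_px < 0 || read_noise_e < 0)
    stop("noise parameters must be non-negative")
  structure(list(background_per_px = background_per_px,
                 read_noise_e = read_noise_e, seed = seed),
            class = "noise_model")
}

#' Frame stack container
#'
#' @param pixels Numeric array `[ny, nx, n_frames]` of non-negative
#'   intensities; row index is y, column index is x, both 0-based in pixel
#'   coordinates (matrix index 1 covers `[0, 1)` px).
#' @param pixel_size_nm Sample-plane pixel pitch (nm).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, pixel_size_nm) {
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L)
    stop("pixels must be a [ny, nx, n_frames] array")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 origin = "px00_halfopen"),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%.1f nm/px)\n",
              d[3], d[2], d[1], x$pixel_size_nm))
  invisible(x)
}

# Pixel-integrated 1D Gaussian profile over pixels lo_px..(hi_px-1)
# (0-based); centers_nm may be a vector, returns [n_px, n_centers].
pixel_profile <- function(centers_nm, sigma_nm, px_nm, lo_px, hi_px) {
  edges <- (lo_px:hi_px) * px_nm
  e <- stats::pnorm(outer(edges, centers_nm, "-") / sigma_nm)
  e[-1, , drop = FALSE] - e[-nrow(e), , drop = FALSE]
}

# Resample a spectrum to quadrature weights at step_nm spacing (sum = 1).
spectrum_weights <- function(spectrum, step_nm = 1) {
  wl <- spectrum$wavelengths_nm
  if (length(wl) == 1L)
    return(list(lambda = wl, w = 1))
  grid <- seq(min(wl), max(wl), by = step_nm)
  w <- stats::approx(wl, spectrum$intensities, xout = grid)$y
  keep <- w > 0
  list(lambda = grid[keep], w = w[keep] / sum(w[keep]))
}

#' Render the noiseless diffraction pair of one emitter
#'
#' The 0th order is a symmetric pixel-integrated 2D Gaussian with the PSF
#' width, carrying `(1 - eta1)` of the photons. The 1st order carries `eta1`
#' of the photons and is the emission spectrum mapped onto the dispersion
#' axis: a quadrature sum (1 nm steps) of symmetric Gaussians displaced by
#' `d(lambda)` along the calibrated axis and weighted by the normalized
#' spectrum. Pixel values are exact integrals of the model over the pixel
#' area, so the total over an unbounded plane equals `photons` exactly.
#'
#' @param em A [emitter()] with a corrected spectrum.
#' @param config An [optical_config()].
#' @param cal A [dispersion_calibration()] supplying `d(lambda)`.
#' @param extent Optional `c(nx, ny)` frame size in pixels; the patch is then
#'   clipped to the frame. By default the patch covers both orders plus a
#'   5 sigma margin.
#' @return A list with `pixels` (patch matrix), `x0_px`, `y0_px` (0-based
#'   offset of the patch in the frame) and `truth` (data frame with the
#'   emitter's `x_nm`, `y_nm`, mean wavelength `lambda_nm`, distance `d_nm`
#'   and the 1st-order center position).
#' @export
render_emitter_patch <- function(em, config, cal, extent = NULL) {
  if (!inherits(em, "sim_emitter")) stop("expected a sim_emitter")
  if (!isTRUE(em$spectrum$corrected))
    stop("emitter spectrum must be transmission-corrected before rendering")
  px <- config$pixel_size_nm
  sigma <- config$psf_sigma_nm
  theta <- cal$axis_deg * pi / 180
  q <- spectrum_weights(em$spectrum, step_nm = 1)
  d_l <- wavelength_to_distance(q$lambda, cal)
  c1x <- em$x_nm + d_l * cos(theta)
  c1y <- em$y_nm + d_l * sin(theta)
  lambda_bar <- weighted_mean_wavelength(em$spectrum)
  d_bar <- wavelength_to_distance(lambda_bar, cal)

  margin <- 5 * sigma
  lo_x <- floor((min(em$x_nm, c1x) - margin) / px)
  hi_x <- ceiling((max(em$x_nm, c1x) + margin) / px)
  lo_y <- floor((min(em$y_nm, c1y) - margin) / px)
  hi_y <- ceiling((max(em$y_nm, c1y) + margin) / px)
  if (!is.null(extent)) {
    lo_x <- max(lo_x, 0); hi_x <- min(hi_x, extent[1])
    lo_y <- max(lo_y, 0); hi_y <- min(hi_y, extent[2])
  }
  if (hi_x <= lo_x || hi_y <= lo_y) {
    return(list(pixels = matrix(0, 0, 0), x0_px = lo_x, y0_px = lo_y,
                truth = NULL))
  }
  eta <- config$first_order_efficiency
  px0 <- pixel_profile(em$x_nm, sigma, px, lo_x, hi_x)
  py0 <- pixel_profile(em$y_nm, sigma, px, lo_y, hi_y)
  patch <- (1 - eta) * em$photons * (py0 %*% t(px0))
  ex <- pixel_profile(c1x, sigma, px, lo_x, hi_x)
  ey <- pixel_profile(c1y, sigma, px, lo_y, hi_y)
  patch <- patch + eta * em$photons *
    (sweep(ey, 2, q$w, "*") %*% t(ex))
  truth <- data.frame(x_nm = em$x_nm, y_nm = em$y_nm,
                      lambda_nm = lambda_bar, d_nm = d_bar,
                      x1_nm = em$x_nm + d_bar * cos(theta),
                      y1_nm = em$y_nm + d_bar * sin(theta))
  list(pixels = patch, x0_px = lo_x, y0_px = lo_y, truth = truth)
}

#' Simulate a stack of camera frames
#'
#' Sums the noiseless diffraction pairs of all emitters active in each frame,
#' adds a uniform background, then applies Poisson shot noise and additive
#' Gaussian read noise. With a fixed `noise$seed` the output is bit-identical
#' across runs.
#'
#' @param emitters A list of [emitter()] objects.
#' @param config An [optical_config()].
#' @param cal A [dispersion_calibration()].
#' @param noise A [noise_model()].
#' @param fov_px `c(nx, ny)` frame size in pixels, both > 0.
#' @param n_frames Number of frames, >= 1.
#' @return A list with `stack` (a [frame_stack()]) and `truth`, a data frame
#'   with one row per active emitter per frame: `frame`, `emitter_id`,
#'   `x_nm`, `y_nm`, `d_nm`, `lambda_nm`, and logical `zeroth_in_fov`,
#'   `first_in_fov` flags (a 1st order can fall outside the field of view
#'   even when its 0th order is inside).
#' @export
simulate_frames <- function(emitters, config, cal, noise = noise_model(),
                            fov_px = c(64, 64), n_frames = 1) {
  if (length(fov_px) != 2 || any(fov_px < 1))
    stop("fov_px must be c(nx, ny) with positive sizes")
  nx <- as.integer(fov_px[1]); ny <- as.integer(fov_px[2])
  if (!is.null(noise$seed)) set.seed(noise$seed)
  px <- config$pixel_size_nm
  patches <- lapply(emitters, render_emitter_patch, config = config,
                    cal = cal, extent = c(nx, ny))
  pixels <- array(0, c(ny, nx, n_frames))
  truth_rows <- list()
  for (f in seq_len(n_frames)) {
    img <- matrix(noise$background_per_px, ny, nx)
    for (i in seq_along(emitters)) {
      em <- emitters[[i]]
      if (f < em$frames[1] || f > em$frames[2]) next
      p <- patches[[i]]
      if (length(p$pixels) > 0) {
        rows <- (p$y0_px + 1):(p$y0_px + nrow(p$pixels))
        cols <- (p$x0_px + 1):(p$x0_px + ncol(p$pixels))
        img[rows, cols] <- img[rows, cols] + p$pixels
      }
      tr <- p$truth
      if (is.null(tr)) {
        tr <- render_emitter_patch(em, config, cal)$truth
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        frame = f, emitter_id = i, x_nm = tr$x_nm, y_nm = tr$y_nm,
        d_nm = tr$d_nm, lambda_nm = tr$lambda_nm,
        zeroth_in_fov = tr$x_nm >= 0 & tr$x_nm < nx * px &
          tr$y_nm >= 0 & tr$y_nm < ny * px,
        first_in_fov = tr$x1_nm >= 0 & tr$x1_nm < nx * px &
          tr$y1_nm >= 0 & tr$y1_nm < ny * px)
    }
    counts <- stats::rpois(length(img), img)
    if (noise$read_noise_e > 0)
      counts <- counts + stats::rnorm(length(img), 0, noise$read_noise_e)
    pixels[, , f] <- counts
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(frame = integer(), emitter_id = integer(), x_nm = numeric(),
               y_nm = numeric(), d_nm = numeric(), lambda_nm = numeric(),
               zeroth_in_fov = logical(), first_in_fov = logical())
  list(stack = frame_stack(pixels, px), truth = truth)
}

#' Predicted 1st-order width along the dispersion axis
#'
#' The 1st-order diffraction pattern is the PSF convolved with the emission
#' spectrum mapped to space, so its standard deviation along the dispersion
#' axis is `sqrt(psf_sigma^2 + (spectrum_sigma / sd)^2)`. The excess over the
#' 0th-order PSF width is therefore a direct measure of the spectral width.
#'
#' @param spectrum A corrected [emission_spectrum()].
#' @param config An [optical_config()].
#' @param cal A [dispersion_calibration()].
#' @return Predicted 1st-order sigma (sample-plane nm).
#' @export
predicted_first_order_width <- function(spectrum, config, cal) {
  if (!isTRUE(spectrum$corrected))
    stop("spectrum must be transmission-corrected")
  sqrt(config$psf_sigma_nm^2 +
         (spectrum_sigma(spectrum) / cal$sd_nm_per_nm)^2)
}
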