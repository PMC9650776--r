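cfg <- optical_config()
cal <- default_calibration()

test_that("a delta-line emitter renders two symmetric Gaussians", {
  sp <- emission_spectrum(692, 1, corrected = TRUE)
  em <- emitter(2000, 1500, sp, photons = 1000)
  p <- render_emitter_patch(em, cfg, cal)
  expect_equal(sum(p$pixels), 1000, tolerance = 1e-6)
  expect_equal(p$truth$d_nm, wavelength_to_distance(692, cal))

  # split the patch at the midpoint between the orders: each half holds 500
  px <- cfg$pixel_size_nm
  mid_col <- round((2000 + p$truth$d_nm / 2) / px) - p$x0_px
  left <- p$pixels[, seq_len(mid_col)]
  right <- p$pixels[, (mid_col + 1):ncol(p$pixels)]
  expect_equal(sum(left), 500, tolerance = 1e-3)
  expect_equal(sum(right), 500, tolerance = 1e-3)

  # 1st order: same widths as the 0th (delta spectrum), centered at x + d
  xs <- (p$x0_px + seq_len(ncol(p$pixels)) - 0.5) * px
  wr <- colSums(right); xr <- xs[(mid_col + 1):ncol(p$pixels)]
  c1 <- sum(wr * xr) / sum(wr)
  s1 <- sqrt(sum(wr * (xr - c1)^2) / sum(wr))
  expect_equal(c1, 2000 + p$truth$d_nm, tolerance = 0.1)
  # pixel binning adds px^2/12 to the measured column-sum variance
  expect_equal(sqrt(s1^2 - px^2 / 12), cfg$psf_sigma_nm, tolerance = 1e-4)
})

test_that("rendering refuses uncorrected spectra and conserves photons", {
  raw <- synth_spectrum(686, 20, skew = 3)
  em_bad <- emitter(2000, 1500, raw)
  expect_error(render_emitter_patch(em_bad, cfg, cal), "corrected")

  sp <- dye_spectrum("CF660")
  em <- emitter(2500, 1500, sp, photons = 1234)
  p <- render_emitter_patch(em, cfg, cal)
  expect_equal(sum(p$pixels), 1234, tolerance = 1e-4)
})

test_that("1st-order width follows the PSF/spectrum quadrature sum", {
  cal2 <- dispersion_calibration(0.2135, 3077, 692)
  sp <- gaussian_spectrum(692, 20)
  # formula vs the independent dense-convolution oracle (<1% error)
  w <- predicted_first_order_width(sp, cfg, cal2)
  expect_equal(w, sqrt(150^2 + (20 / 0.2135)^2), tolerance = 1e-6)
  expect_equal(w, 176.9, tolerance = 1e-3)
  orc <- oracle_first_order_sigma(sp, cal2, cfg$psf_sigma_nm)
  expect_lt(abs(w - orc) / orc, 0.01)

  # rendered patch second moment agrees with the prediction
  em <- emitter(2000, 1500, sp, photons = 1e5)
  p <- render_emitter_patch(em, cfg, cal2)
  px <- cfg$pixel_size_nm
  mid_col <- round((2000 + p$truth$d_nm / 2) / px) - p$x0_px
  right <- p$pixels[, (mid_col + 1):ncol(p$pixels)]
  xs <- (p$x0_px + (mid_col + 1):ncol(p$pixels) - 0.5) * px
  wr <- colSums(right)
  c1 <- sum(wr * xs) / sum(wr)
  s1 <- sqrt(sum(wr * (xs - c1)^2) / sum(wr))
  # pixel integration adds a px^2/12 variance term; remove it before comparing
  expect_equal(sqrt(s1^2 - px^2 / 12), w, tolerance = 5e-3)

  delta <- emission_spectrum(692, 1, corrected = TRUE)
  expect_equal(predicted_first_order_width(delta, cfg, cal2),
               cfg$psf_sigma_nm)
})

test_that("narrow spectra put the 1st-order centroid at d(lambda_bar)", {
  for (sig in c(2, 5)) {
    sp <- gaussian_spectrum(690, sig)
    em <- emitter(2000, 1500, sp, photons = 1e5)
    p <- render_emitter_patch(em, cfg, cal)
    px <- cfg$pixel_size_nm
    mid_col <- round((2000 + p$truth$d_nm / 2) / px) - p$x0_px
    right <- p$pixels[, (mid_col + 1):ncol(p$pixels)]
    xs <- (p$x0_px + (mid_col + 1):ncol(p$pixels) - 0.5) * px
    c1 <- sum(colSums(right) * xs) / sum(right)
    expect_lt(abs(c1 - (2000 + p$truth$d_nm)), 0.5)
  }
})

test_that("simulate_frames is deterministic, noise-free when asked, and flags the FOV", {
  sp <- dye_spectrum("CF660")
  quiet <- noise_model(background_per_px = 0, read_noise_e = 0, seed = 3)
  empty <- simulate_frames(list(), cfg, cal, quiet, fov_px = c(16, 16),
                           n_frames = 2)
  expect_true(all(empty$stack$pixels == 0))
  expect_equal(nrow(empty$truth), 0)

  em <- emitter(1200, 1000, sp, photons = 800)
  a <- simulate_frames(list(em), cfg, cal, noise_model(seed = 9),
                       fov_px = c(48, 20), n_frames = 3)
  b <- simulate_frames(list(em), cfg, cal, noise_model(seed = 9),
                       fov_px = c(48, 20), n_frames = 3)
  expect_identical(a$stack$pixels, b$stack$pixels)

  # 0th inside, 1st outside a narrow FOV
  clipped <- simulate_frames(list(em), cfg, cal, quiet, fov_px = c(24, 20))
  expect_true(clipped$truth$zeroth_in_fov)
  expect_false(clipped$truth$first_in_fov)

  # blinking: frame range respected
  em2 <- emitter(1200, 1000, sp, photons = 800, frames = c(2, 2))
  s <- simulate_frames(list(em2), cfg, cal, quiet, fov_px = c(48, 20),
                       n_frames = 3)
  expect_equal(s$truth$frame, 2)
  expect_true(all(s$stack$pixels[, , 1] == 0))
  expect_gt(sum(s$stack$pixels[, , 2]), 700)
})

test_that("noisy frames average to the noiseless expectation", {
  sp <- gaussian_spectrum(692, 15)
  em <- emitter(800, 600, sp, photons = 600)
  p <- render_emitter_patch(em, cfg, cal, extent = c(40, 12))
  noiseless <- matrix(0, 12, 40)
  noiseless[(p$y0_px + 1):(p$y0_px + nrow(p$pixels)),
            (p$x0_px + 1):(p$x0_px + ncol(p$pixels))] <- p$pixels
  noisy <- simulate_frames(list(em), cfg, cal,
                           noise_model(2, 1, seed = 7), fov_px = c(40, 12),
                           n_frames = 300)
  avg <- apply(noisy$stack$pixels, c(1, 2), mean)
  expected <- noiseless + 2
  se <- sqrt(expected + 1) / sqrt(300)
  frac_bad <- mean(abs(avg - expected) > 4 * se)
  expect_lt(frac_bad, 0.005)
})
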