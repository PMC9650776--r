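test_that("emission_spectrum validates its invariants", {
  expect_error(emission_spectrum(c(650, 640), c(1, 1)), "increasing")
  expect_error(emission_spectrum(c(640, 650), c(-1, 1)), "non-negative")
  expect_error(emission_spectrum(c(640, 650), c(0, 0)), "positive")
  expect_error(emission_spectrum(650, 1, quantum_yield = 1.2), "quantum_yield")
  expect_s3_class(emission_spectrum(650, 1), "emission_spectrum")  # delta line
})

test_that("apply_transmission multiplies pointwise and flags correction", {
  sp <- gaussian_spectrum(680, 15)
  sp$corrected <- FALSE
  flat <- transmission_profile(c(400, 900), c(1, 1))
  out <- apply_transmission(sp, flat)
  expect_equal(out$intensities, sp$intensities)
  expect_true(out$corrected)
  expect_error(apply_transmission(out, flat), "already")

  delta <- emission_spectrum(650, 2.0)
  half <- transmission_profile(c(600, 700), c(0.5, 0.5))
  out2 <- apply_transmission(delta, half)
  expect_equal(out2$intensities, 1.0)
  expect_equal(weighted_mean_wavelength(out2), 650)
})

test_that("transmission x ramp shifts the weighted mean as the oracle says", {
  sp <- synth_spectrum(680, 15, skew = 0, grid = seq(600, 800, by = 1))
  ramp <- transmission_profile(c(600, 800), c(0.2, 1))
  out <- apply_transmission(sp, ramp)
  expect_gt(weighted_mean_wavelength(out), weighted_mean_wavelength(sp))
  tr <- approx(c(600, 800), c(0.2, 1), xout = seq(600, 800, by = 0.1))$y
  orc <- oracle_moments(seq(600, 800, by = 0.1),
                        approx(sp$wavelengths_nm, sp$intensities,
                               seq(600, 800, by = 0.1))$y * tr)
  expect_equal(weighted_mean_wavelength(out), orc$mean, tolerance = 1e-3)
})

test_that("transmission never increases the integrated intensity", {
  set.seed(11)
  for (i in 1:10) {
    sp <- synth_spectrum(runif(1, 600, 720), runif(1, 10, 30),
                         skew = runif(1, 0, 4))
    tp <- transmission_profile(seq(500, 900, by = 10),
                               runif(41, 0.1, 1))
    out <- apply_transmission(sp, tp)
    expect_lte(oracle_trapz(out$wavelengths_nm, out$intensities),
               oracle_trapz(sp$wavelengths_nm, sp$intensities) * (1 + 1e-12))
  }
})

test_that("out-of-band and blocked spectra error clearly", {
  sp <- emission_spectrum(c(640, 650, 660), c(1, 2, 1))
  expect_error(apply_transmission(sp, transmission_profile(c(400, 500), c(1, 1))),
               "unusable")
  expect_error(apply_transmission(sp, transmission_profile(c(600, 700), c(0, 0))),
               "blocks")
})

test_that("weighted mean, peak, and sigma behave on reference shapes", {
  delta <- emission_spectrum(650, 1)
  expect_equal(weighted_mean_wavelength(delta), 650)
  expect_equal(peak_wavelength(delta), 650)
  expect_equal(spectrum_sigma(delta), 0)

  two <- emission_spectrum(c(640, 660), c(1, 1))
  expect_equal(weighted_mean_wavelength(two), 650)
  expect_equal(spectrum_sigma(two), 10)

  g <- synth_spectrum(680, 15, skew = 0, grid = seq(600, 800, by = 0.5))
  expect_equal(weighted_mean_wavelength(g), 680, tolerance = 1e-4)
  expect_equal(spectrum_sigma(g), 15, tolerance = 1e-3)
  expect_equal(peak_wavelength(g), 680, tolerance = 0.5)

  bimodal <- emission_spectrum(c(660, 680, 700), c(1.0, 0.1, 0.9))
  expect_equal(peak_wavelength(bimodal), 660)  # global max, shorter wins

  scaled <- emission_spectrum(g$wavelengths_nm, g$intensities * 37.5)
  expect_equal(weighted_mean_wavelength(scaled), weighted_mean_wavelength(g))
  expect_equal(spectrum_sigma(scaled), spectrum_sigma(g))
})

test_that("synth_spectrum places the mode at peak_nm and skews the mean", {
  s0 <- synth_spectrum(686, 20, skew = 0)
  expect_equal(weighted_mean_wavelength(s0), 686, tolerance = 1e-3)
  expect_equal(peak_wavelength(s0), 686, tolerance = 1)

  s4 <- synth_spectrum(686, 20, skew = 4)
  expect_gt(weighted_mean_wavelength(s4), peak_wavelength(s4))
  # oracle: dense-grid moments of the skew-normal density itself
  m0 <- optimize(function(x) oracle_skew_normal(x, 0, 1, 4), c(-4, 4),
                 maximum = TRUE, tol = 1e-9)$maximum
  xi <- 686 - 20 * m0
  g <- seq(xi - 120, xi + 160, by = 0.1)
  orc <- oracle_moments(g, oracle_skew_normal(g, xi, 20, 4), step = 0.1)
  expect_equal(weighted_mean_wavelength(s4), orc$mean, tolerance = 0.05)
  expect_error(synth_spectrum(686, -1), "positive")
})

test_that("fret_mixed_spectrum interpolates between donor and acceptor", {
  donor <- gaussian_spectrum(575, 25, qy = 0.8)
  acceptor <- gaussian_spectrum(665, 20, qy = 0.65)
  m0 <- fret_mixed_spectrum(donor, acceptor, 0)
  m1 <- fret_mixed_spectrum(donor, acceptor, 1)
  expect_equal(weighted_mean_wavelength(m0),
               weighted_mean_wavelength(donor), tolerance = 1e-6)
  expect_equal(weighted_mean_wavelength(m1),
               weighted_mean_wavelength(acceptor), tolerance = 1e-6)

  es <- c(0, 0.15, 0.55, 0.8, 1)
  means <- vapply(es, function(E)
    weighted_mean_wavelength(fret_mixed_spectrum(donor, acceptor, E)),
    numeric(1))
  expect_true(all(diff(means) > 0))

  # E = 0.55 against an independent dense-grid mixing oracle
  g <- seq(450, 800, by = 0.1)
  sd_ <- function(sp) {
    y <- approx(sp$wavelengths_nm, sp$intensities, xout = g)$y
    y[is.na(y)] <- 0
    y / oracle_trapz(g, y)
  }
  mix <- 0.45 * 0.8 * sd_(donor) + 0.55 * 0.65 * sd_(acceptor)
  orc <- oracle_moments(g, mix, step = 0.1)
  got <- weighted_mean_wavelength(fret_mixed_spectrum(donor, acceptor, 0.55))
  expect_equal(got, orc$mean, tolerance = 0.05)
  expect_gt(got, weighted_mean_wavelength(donor))
  expect_lt(got, weighted_mean_wavelength(acceptor))

  expect_error(fret_mixed_spectrum(donor, acceptor, 1.2), "efficiency")
  raw <- synth_spectrum(575, 25)
  expect_error(fret_mixed_spectrum(raw, acceptor, 0.5), "corrected")
})

test_that("Foerster relation evaluates and validates", {
  expect_equal(fret_efficiency_from_distance(6.3, 6.3), 0.5)
  expect_equal(fret_efficiency_from_distance(8.4, 6.3), 1 / (1 + (8.4 / 6.3)^6))
  expect_equal(fret_efficiency_from_distance(8.4, 6.3), 0.151, tolerance = 0.001)
  expect_equal(fret_efficiency_from_distance(5.9, 6.3), 0.597, tolerance = 0.001)
  expect_error(fret_efficiency_from_distance(-1, 6.3), "positive")
})
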