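# Independent numerical oracles used by the tests. These deliberately avoid
# the package's own integration/convolution code paths: everything here is
# dense-grid quadrature or closed-form evaluation.

# Trapezoidal integral on a dense grid (0.1 nm unless stated otherwise).
oracle_trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

# Moments of a tabulated spectrum by dense-grid resampling + quadrature.
oracle_moments <- function(wl, intens, step = 0.1) {
  g <- seq(min(wl), max(wl), by = step)
  s <- approx(wl, intens, xout = g)$y
  total <- oracle_trapz(g, s)
  m1 <- oracle_trapz(g, g * s) / total
  m2 <- oracle_trapz(g, (g - m1)^2 * s) / total
  list(mean = m1, sigma = sqrt(m2), total = total)
}

# Skew-normal density (direct formula, independent of synth_spectrum).
oracle_skew_normal <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

# Dense 1D convolution oracle for the 1st-order profile: spectrum mapped to
# space through the calibration, convolved with a Gaussian PSF; returns the
# standard deviation of the resulting profile.
oracle_first_order_sigma <- function(spec, cal, psf_sigma_nm, step = 0.5) {
  wl <- spec$wavelengths_nm
  g <- seq(min(wl), max(wl), by = 0.1)
  s <- approx(wl, spec$intensities, xout = g)$y
  pos <- cal$anchor_distance_nm + (g - cal$anchor_wavelength_nm) / cal$sd_nm_per_nm
  x <- seq(min(pos) - 6 * psf_sigma_nm, max(pos) + 6 * psf_sigma_nm,
           by = step)
  prof <- vapply(x, function(xx)
    oracle_trapz(g, s * dnorm(xx - pos, sd = psf_sigma_nm)), numeric(1))
  total <- oracle_trapz(x, prof)
  m1 <- oracle_trapz(x, x * prof) / total
  sqrt(oracle_trapz(x, (x - m1)^2 * prof) / total)
}

# Closed-form bivariate normal density via explicit matrix algebra
# (independent of the package's dmvnorm2).
oracle_dmvnorm <- function(x, mean, cov) {
  d <- x - mean
  as.numeric(exp(-0.5 * t(d) %*% solve(cov) %*% d) /
               (2 * pi * sqrt(det(cov))))
}

# Exhaustive minimum-lateral-cost matching of two point sets along the
# dispersion axis (brute force over all injective assignments; oracle for
# link_orders on small frames).
oracle_best_matching <- function(locs, d_window, lateral_tol, theta = 0) {
  n <- nrow(locs)
  ux <- cos(theta); uy <- sin(theta)
  pairs <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    dx <- locs$x_nm[b] - locs$x_nm[a]; dy <- locs$y_nm[b] - locs$y_nm[a]
    proj <- dx * ux + dy * uy; lat <- -dx * uy + dy * ux
    if (proj >= d_window[1] && proj <= d_window[2] &&
        abs(lat) <= lateral_tol)
      pairs[[length(pairs) + 1L]] <- c(a, b, abs(lat))
  }
  if (!length(pairs)) return(matrix(numeric(0), ncol = 2))
  pm <- do.call(rbind, pairs)
  best <- NULL; best_score <- Inf
  n_cand <- nrow(pm)
  # enumerate subsets of candidate links (small n only)
  for (mask in seq_len(2^n_cand) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n_cand) - 1)) > 0)
    used <- c(pm[sel, 1], pm[sel, 2])
    if (anyDuplicated(used)) next
    score <- c(-length(sel) * 1e9 + sum(pm[sel, 3]))
    if (score < best_score) { best_score <- score; best <- pm[sel, 1:2, drop = FALSE] }
  }
  best
}

default_test_config <- function(...) optical_config(...)
default_test_cal <- function() default_calibration()

# Vectorized diagonal-free bivariate normal (for the misclassification
# oracle); accepts a full 2x2 covariance.
dmvnorm_vec <- function(x, y, mean, cov) {
  det_ <- cov[1, 1] * cov[2, 2] - cov[1, 2]^2
  dx <- x - mean[1]; dy <- y - mean[2]
  q <- (cov[2, 2] * dx^2 - 2 * cov[1, 2] * dx * dy + cov[1, 1] * dy^2) / det_
  exp(-q / 2) / (2 * pi * sqrt(det_))
}

empty_pairs_df <- function() {
  data.frame(x0_nm = numeric(0), y0_nm = numeric(0), d_nm = numeric(0),
             label = character(0))
}

# Gaussian-shaped corrected spectrum centered at a given mean wavelength.
gaussian_spectrum <- function(mean_nm, sigma_nm, qy = 1) {
  synth_spectrum(mean_nm, sigma_nm, skew = 0, quantum_yield = qy,
                 corrected = TRUE)
}
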