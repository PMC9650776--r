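#' Monte-Carlo achievable-emitter-density experiment
#'
#' Quantifies how many simultaneously active emitters per square micrometre
#' remain individually resolvable and linkable, for three detection modes:
#'
#' * `standard`: non-spectrally-resolved SMLM (only the 0th-order PSF
#'   occupies space);
#' * `low_dispersion`: this package's approach, where each emitter
#'   additionally produces a slightly elongated 1st-order pattern one
#'   0th-to-1st-order distance away;
#' * `comparator`: a conventional dispersive sSMLM layout whose spectral
#'   pattern is elongated over `comparator_spread_px` camera pixels.
#'
#' The resolvability criterion is an explicit rectangular exclusion
#' footprint: the 0th order claims a `(6 psf_sigma)^2` square, the 1st order
#' a `(6 psf_sigma + spread) x (6 psf_sigma)` rectangle along/across the
#' dispersion axis, where `spread` is the spectral elongation (for the
#' low-dispersion mode, the `4 sigma_lambda / sd` extent of a reference
#' spectrum; for the comparator, `comparator_spread_px` pixels). An emitter
#' is resolvable iff none of its footprints intersects a footprint of a
#' *different* emitter. Emitters are placed uniformly at random on a periodic
#' field of view (torus), which removes edge bias from the density estimate.
#' The achievable density is the largest density at which the mean resolvable
#' fraction still meets `resolve_threshold` (linearly interpolated between
#' evaluated densities).
#'
#' @param config An [optical_config()].
#' @param cal A [dispersion_calibration()]; its anchor distance sets the
#'   0th-to-1st-order offset used for the footprints.
#' @param densities Emitter densities to evaluate (emitters per um^2), > 0.
#' @param comparator_spread_px Spectral elongation of the comparator mode in
#'   camera pixels, >= 1.
#' @param fov_um `c(width, height)` of the simulated field of view (um).
#' @param n_rep Monte-Carlo repetitions per density.
#' @param resolve_threshold Resolvable fraction defining "achievable".
#' @param spectral_sigma_nm Spectral standard deviation of the reference
#'   emission spectrum used to size the low-dispersion elongation (nm).
#' @param seed Optional integer seed.
#' @return A list with `curves` (data frame: `mode`, `density`, `fraction`,
#'   `fraction_sd`) and `achievable` (data frame: `mode`, `density`), both
#'   in emitters per um^2.
#' @export
density_experiment <- function(config, cal,
                               densities = 10^seq(-2, 0, length.out = 9),
                               comparator_spread_px = 25,
                               fov_um = c(30, 30), n_rep = 8,
                               resolve_threshold = 0.5,
                               spectral_sigma_nm = 20, seed = NULL) {
  if (any(densities <= 0)) stop("densities must be positive")
  if (comparator_spread_px < 1) stop("comparator spread must be >= 1 px")
  if (!is.null(seed)) set.seed(seed)
  densities <- sort(densities)
  s6 <- 6 * config$psf_sigma_nm / 1000          # footprint side, um
  d_off <- cal$anchor_distance_nm / 1000        # 0th-to-1st offset, um
  spread_low <- 4 * spectral_sigma_nm / cal$sd_nm_per_nm / 1000
  spread_cmp <- comparator_spread_px * config$pixel_size_nm / 1000
  modes <- list(
    standard = NULL,
    low_dispersion = spread_low,
    comparator = spread_cmp)

  curves <- list()
  for (mode in names(modes)) {
    spread <- modes[[mode]]
    for (rho in densities) {
      fr <- vapply(seq_len(n_rep), function(r)
        resolvable_fraction(rho, fov_um, s6, d_off, spread), numeric(1))
      curves[[length(curves) + 1L]] <- data.frame(
        mode = mode, density = rho, fraction = mean(fr),
        fraction_sd = stats::sd(fr))
    }
  }
  curves <- do.call(rbind, curves)
  achievable <- do.call(rbind, lapply(names(modes), function(mode) {
    cc <- curves[curves$mode == mode, ]
    data.frame(mode = mode,
               density = crossing_density(cc$density, cc$fraction,
                                          resolve_threshold))
  }))
  list(curves = curves, achievable = achievable)
}

# Largest density with fraction >= threshold, linearly interpolated in
# log-density at the crossing; NA if the first density is already below,
# max(density) if the curve never drops below.
crossing_density <- function(density, fraction, threshold) {
  above <- fraction >= threshold
  if (!above[1]) return(NA_real_)
  if (all(above)) return(max(density))
  i <- which(!above)[1]  # first density below threshold
  x1 <- log(density[i - 1]); x2 <- log(density[i])
  f1 <- fraction[i - 1]; f2 <- fraction[i]
  exp(x1 + (threshold - f1) * (x2 - x1) / (f2 - f1))
}

# One Monte-Carlo realization of the footprint-overlap criterion on a torus.
# spread = NULL -> standard SMLM (no 1st-order footprint).
resolvable_fraction <- function(rho, fov_um, s6, d_off, spread) {
  w <- fov_um[1]; h <- fov_um[2]
  n <- max(2L, round(rho * w * h))
  x <- stats::runif(n, 0, w)
  y <- stats::runif(n, 0, h)
  # rectangles: centers, widths (x along dispersion axis), heights
  cx <- list(x); cy <- list(y); rw <- list(rep(s6, n))
  if (!is.null(spread)) {
    cx <- c(cx, list((x + d_off + spread / 2) %% w))
    cy <- c(cy, list(y))
    rw <- c(rw, list(rep(s6 + spread, n)))
  }
  conflict <- rep(FALSE, n)
  for (a in seq_along(cx)) for (b in seq_along(cx)) {
    dx <- abs(outer(cx[[a]], cx[[b]], "-")); dx <- pmin(dx, w - dx)
    dy <- abs(outer(cy[[a]], cy[[b]], "-")); dy <- pmin(dy, h - dy)
    half_w <- outer(rw[[a]], rw[[b]], "+") / 2
    ov <- dx < half_w & dy < s6
    diag(ov) <- FALSE  # an emitter's own footprints never conflict
    conflict <- conflict | rowSums(ov) > 0
  }
  mean(!conflict)
}
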