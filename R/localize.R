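#' Detect candidate diffraction patterns in a frame
#'
#' Standard SMLM detection stage: the frame is smoothed with a Gaussian
#' kernel matched to the PSF, and local maxima exceeding
#' `median + threshold_factor * robust noise` (noise estimated as the MAD of
#' the smoothed frame) are returned. Maxima closer than `min_sep_px` are
#' suppressed keeping the brighter one.
#'
#' @param frame Numeric matrix (one camera frame; rows = y, cols = x).
#' @param psf_sigma_px PSF standard deviation in pixels, > 0.
#' @param threshold_factor Detection threshold in robust-noise units.
#' @param min_sep_px Minimum separation between candidates (px).
#' @return A data frame with integer 1-based matrix indices `row`, `col` and
#'   the smoothed `intensity`; zero rows if nothing is found.
#' @export
detect_candidates <- function(frame, psf_sigma_px, threshold_factor = 5,
                              min_sep_px = 2) {
  sm <- gauss_smooth(frame, psf_sigma_px)
  thr <- stats::median(sm) + threshold_factor * stats::mad(sm)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3 || nc < 3) return(empty_candidates())
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= sm[2:(nr - 1) + di, 2:(nc - 1) + dj]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_candidates())
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     intensity = core[idx])
  cand <- cand[order(-cand$intensity), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    too_close <- keep & seq_len(nrow(cand)) > i &
      abs(cand$row - cand$row[i]) < min_sep_px &
      abs(cand$col - cand$col[i]) < min_sep_px
    keep[too_close] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

empty_candidates <- function() {
  data.frame(row = integer(), col = integer(), intensity = numeric())
}

# Separable Gaussian smoothing with edge renormalization.
gauss_smooth <- function(frame, sigma_px) {
  r <- max(1L, ceiling(2.5 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
      out <- out + k[o + r + 1] * m[src, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(frame))))
}

# Pixel-integrated Gaussian model on a window, 0-based continuous px coords.
# Returns the expected counts for parameters (x, y, sx, sy, N, b).
window_model <- function(x, y, sx, sy, N, b, nx, ny) {
  gx <- diff(stats::pnorm((0:nx - x) / sx))
  gy <- diff(stats::pnorm((0:ny - y) / sy))
  b + N * (gy %*% t(gx))
}

#' Fit one diffraction pattern with a sub-pixel Gaussian model
#'
#' Maximum-likelihood fit (Poisson noise model) of a pixel-integrated 2D
#' Gaussian plus a local constant background, in a rectangular window around
#' a detected candidate. The `symmetric` model ties the two widths (0th-order
#' PSF); the `elongated` model frees the width along the dispersion axis
#' (1st-order pattern). Localization precision is the square root of the
#' Cramer-Rao bound from the Fisher information of the fitted model; the
#' reported `uncertainty_nm` is the bound along the dispersion axis, the
#' direction that carries the spectral information.
#'
#' Fits that do not converge, or whose center drifts more than half the
#' window from the candidate, are rejected (`NULL` with a diagnostic
#' attribute is returned).
#'
#' @param frame Numeric matrix (one camera frame).
#' @param candidate One row of [detect_candidates()] output (or a list with
#'   `row`, `col`).
#' @param pixel_size_nm Sample-plane pixel pitch (nm).
#' @param model `"elongated"` (default) or `"symmetric"`.
#' @param window_px `c(wx, wy)` window size in pixels (odd values center the
#'   window on the candidate). The default 11 x 7 covers +/-3 PSF sigma plus
#'   the 2-3 px elongation of a low-dispersion 1st order.
#' @param psf_sigma_px Initial width guess (px).
#' @return A one-row data frame with columns `frame`, `x_nm`, `y_nm`,
#'   `sigma_x_nm`, `sigma_y_nm`, `photons`, `background`, `uncertainty_nm`,
#'   `order`; or a `rejected_fit` object (see [is_rejected_fit()]) carrying
#'   the diagnostic code.
#' @export
fit_psf <- function(frame, candidate, pixel_size_nm,
                    model = c("elongated", "symmetric"),
                    window_px = c(11, 7), psf_sigma_px = 1.2) {
  model <- match.arg(model)
  hw <- floor(window_px[1] / 2); hh <- floor(window_px[2] / 2)
  r0 <- candidate$row; c0 <- candidate$col
  rows <- max(1, r0 - hh):min(nrow(frame), r0 + hh)
  cols <- max(1, c0 - hw):min(ncol(frame), c0 + hw)
  win <- frame[rows, cols, drop = FALSE]
  win <- pmax(win, 0)
  ny <- nrow(win); nx <- ncol(win)
  if (nx < 4 || ny < 4) return(reject_fit("window_truncated"))

  bg0 <- max(stats::median(c(win[1, ], win[ny, ], win[, 1], win[, nx])), 0.1)
  sig <- pmax(win - bg0, 0)
  tot <- sum(sig)
  if (tot <= 0) return(reject_fit("no_signal"))
  x0 <- sum(sig %*% (seq_len(nx) - 0.5)) / tot
  y0 <- sum((seq_len(ny) - 0.5) %*% sig) / tot

  tied <- model == "symmetric"
  # parameters: x, y, log sx, [log sy], log N, log b
  p0 <- c(x0, y0, log(psf_sigma_px),
          if (!tied) log(psf_sigma_px), log(max(tot, 1)), log(bg0))
  unpack <- function(p) {
    sx <- exp(p[3])
    sy <- if (tied) sx else exp(p[4])
    k <- if (tied) 4 else 5
    list(x = p[1], y = p[2], sx = sx, sy = sy,
         N = exp(p[k]), b = exp(p[k + 1]))
  }
  nll <- function(p) {
    q <- unpack(p)
    mu <- window_model(q$x, q$y, q$sx, q$sy, q$N, q$b, nx, ny)
    sum(mu) - sum(win * log(mu))
  }
  lower <- c(-1, -1, log(0.3), if (!tied) log(0.3), log(1), log(1e-3))
  upper <- c(nx + 1, ny + 1, log(nx), if (!tied) log(ny),
             log(1e9), log(1e6))
  fit <- tryCatch(
    stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(reject_fit("optim_error"))
  if (!all(is.finite(fit$par))) return(reject_fit("non_finite"))
  if (fit$convergence != 0 && fit$convergence != 1)
    return(reject_fit("no_convergence"))
  q <- unpack(fit$par)
  if (abs(q$x - x0) > nx / 2 || abs(q$y - y0) > ny / 2)
    return(reject_fit("fit_drift"))

  unc_px <- fisher_position_bound(q, nx, ny)
  x_nm <- (cols[1] - 1 + q$x) * pixel_size_nm
  y_nm <- (rows[1] - 1 + q$y) * pixel_size_nm
  out <- data.frame(frame = NA_integer_, x_nm = x_nm, y_nm = y_nm,
                    sigma_x_nm = q$sx * pixel_size_nm,
                    sigma_y_nm = q$sy * pixel_size_nm,
                    photons = q$N, background = q$b,
                    uncertainty_nm = unc_px * pixel_size_nm,
                    order = "unknown", stringsAsFactors = FALSE)
  out
}

reject_fit <- function(reason) {
  structure(list(reason = reason), class = "rejected_fit")
}

#' Was a fit rejected?
#' @param x Result of [fit_psf()].
#' @return `TRUE` if the fit was rejected; the diagnostic code is in
#'   `x$reason`.
#' @export
is_rejected_fit <- function(x) inherits(x, "rejected_fit")

# Cramer-Rao bound on the fitted x position (dispersion axis) for the
# Poisson pixel-integrated Gaussian model, via numeric Fisher information
# over (x, y, sx, sy, N, b).
fisher_position_bound <- function(q, nx, ny) {
  p <- c(q$x, q$y, q$sx, q$sy, q$N, q$b)
  mu_of <- function(p) window_model(p[1], p[2], p[3], p[4], p[5], p[6], nx, ny)
  mu <- mu_of(p)
  eps <- pmax(abs(p), 0.1) * 1e-4
  J <- vapply(seq_along(p), function(k) {
    ph <- p; ph[k] <- ph[k] + eps[k]
    pl <- p; pl[k] <- pl[k] - eps[k]
    as.numeric((mu_of(ph) - mu_of(pl)) / (2 * eps[k]))
  }, numeric(length(mu)))
  info <- crossprod(J / sqrt(as.numeric(mu)))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || cov[1, 1] <= 0) return(NA_real_)
  sqrt(cov[1, 1])
}

#' Localize every diffraction pattern in a frame stack
#'
#' Runs [detect_candidates()] and [fit_psf()] on every frame. Rejected fits
#' are skipped (counted in the `rejected` attribute), never abort the stack.
#' Duplicate fits within 1 px are merged keeping the higher-photon one. By
#' default every candidate is fitted with the elongated model: a fitted
#' `sigma_x ~ sigma_y` then indicates a 0th order, while the order label is
#' left `"unknown"` for the pairing stage to assign.
#'
#' @param stack A [frame_stack()].
#' @param config An [optical_config()].
#' @param params Optional list overriding `threshold_factor`, `window_px`,
#'   `model`, `min_sep_px`.
#' @return A data frame of localizations (columns as in [fit_psf()]),
#'   ordered by frame then x, with attribute `rejected` (named counts of
#'   rejection reasons).
#' @export
localize_stack <- function(stack, config, params = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  p <- utils::modifyList(list(threshold_factor = 5, window_px = c(11, 7),
                              model = "elongated", min_sep_px = 2), params)
  px <- stack$pixel_size_nm
  psf_px <- config$psf_sigma_nm / px
  n_frames <- dim(stack$pixels)[3]
  rows <- list()
  rejected <- numeric(0)
  for (f in seq_len(n_frames)) {
    frame <- stack$pixels[, , f]
    cand <- detect_candidates(frame, psf_px, p$threshold_factor,
                              p$min_sep_px)
    for (i in seq_len(nrow(cand))) {
      loc <- fit_psf(frame, cand[i, ], px, model = p$model,
                     window_px = p$window_px, psf_sigma_px = psf_px)
      if (is_rejected_fit(loc)) {
        r <- loc$reason
        rejected[r] <- if (r %in% names(rejected)) rejected[r] + 1 else 1
        next
      }
      loc$frame <- f
      rows[[length(rows) + 1L]] <- loc
    }
  }
  locs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
               sigma_x_nm = numeric(), sigma_y_nm = numeric(),
               photons = numeric(), background = numeric(),
               uncertainty_nm = numeric(), order = character(),
               stringsAsFactors = FALSE)
  locs <- merge_duplicates(locs, tol_nm = px)
  locs <- locs[order(locs$frame, locs$x_nm), ]
  rownames(locs) <- NULL
  attr(locs, "rejected") <- rejected
  locs
}

# Merge localizations of the same frame closer than tol, keeping the
# higher-photon fit.
merge_duplicates <- function(locs, tol_nm) {
  if (nrow(locs) < 2) return(locs)
  keep <- rep(TRUE, nrow(locs))
  ord <- order(-locs$photons)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (!keep[j] || locs$frame[j] != locs$frame[i]) next
      if (abs(locs$x_nm[j] - locs$x_nm[i]) < tol_nm &&
          abs(locs$y_nm[j] - locs$y_nm[i]) < tol_nm)
        keep[j] <- FALSE
    }
  }
  locs[keep, , drop = FALSE]
}
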