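#' Link 0th- and 1st-order localizations into spectral pairs
#'
#' For each frame, every ordered pair of localizations (A, B) with B
#' displaced from A along the positive dispersion axis is a linking
#' candidate when the projected distance lies in `d_window` and the
#' perpendicular (lateral) offset is within `lateral_tol_nm`. Candidates are
#' accepted greedily in order of ascending lateral offset (ties broken by
#' distance to the window center), each localization used at most once —
#' an injective partial matching that is deterministic and independent of
#' input order. A is relabeled `zeroth`, B `first`. Localizations left over
#' (e.g. a 0th order whose 1st order fell outside the field of view) are
#' returned unpaired.
#'
#' The default window (2200, 3600) nm covers the distances of common
#' red-emitting dyes on the default instrument (~2600-3130 nm) with margin.
#'
#' @param locs Localization data frame (see [localize_stack()]).
#' @param cal A [dispersion_calibration()] (supplies the axis angle and the
#'   distance-to-wavelength map).
#' @param d_window `c(min, max)` accepted projected distance (nm).
#' @param lateral_tol_nm Maximum perpendicular offset (nm).
#' @return A list with `pairs` (data frame: `frame`, `x0_nm`, `y0_nm`,
#'   `x1_nm`, `y1_nm`, `d_nm`, `lateral_nm`, `sigma0_nm`, `sigma1_nm`,
#'   `sigma_excess_nm`, `lambda_nm`, `unc0_nm`, `unc1_nm`, `photons0`,
#'   `photons1`, `label`) and `unpaired` (the leftover localization rows).
#' @export
link_orders <- function(locs, cal, d_window = c(2200, 3600),
                        lateral_tol_nm = 150) {
  if (d_window[1] >= d_window[2]) stop("d_window must satisfy min < max")
  theta <- cal$axis_deg * pi / 180
  ux <- cos(theta); uy <- sin(theta)
  pair_rows <- list()
  used <- rep(FALSE, nrow(locs))
  if (nrow(locs) > 0) for (f in unique(locs$frame)) {
    idx <- which(locs$frame == f)
    if (length(idx) < 2) next
    dx <- outer(locs$x_nm[idx], locs$x_nm[idx], function(a, b) b - a)
    dy <- outer(locs$y_nm[idx], locs$y_nm[idx], function(a, b) b - a)
    proj <- dx * ux + dy * uy
    lat <- -dx * uy + dy * ux
    ok <- proj >= d_window[1] & proj <= d_window[2] &
      abs(lat) <= lateral_tol_nm
    diag(ok) <- FALSE
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    score_lat <- abs(lat[cand])
    score_ctr <- abs(proj[cand] - mean(d_window))
    ord <- order(score_lat, score_ctr)
    taken <- rep(FALSE, length(idx))
    for (k in ord) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (taken[a] || taken[b]) next
      taken[a] <- TRUE; taken[b] <- TRUE
      ia <- idx[a]; ib <- idx[b]
      used[c(ia, ib)] <- TRUE
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        frame = f,
        x0_nm = locs$x_nm[ia], y0_nm = locs$y_nm[ia],
        x1_nm = locs$x_nm[ib], y1_nm = locs$y_nm[ib],
        d_nm = proj[a, b], lateral_nm = lat[a, b],
        sigma0_nm = locs$sigma_x_nm[ia], sigma1_nm = locs$sigma_x_nm[ib],
        sigma_excess_nm = NA_real_, lambda_nm = NA_real_,
        unc0_nm = locs$uncertainty_nm[ia], unc1_nm = locs$uncertainty_nm[ib],
        photons0 = locs$photons[ia], photons1 = locs$photons[ib],
        label = NA_character_, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    empty_pairs()
  pairs <- pair_observables(pairs, cal)
  unpaired <- locs[!used, , drop = FALSE]
  list(pairs = pairs, unpaired = unpaired)
}

empty_pairs <- function() {
  data.frame(frame = integer(), x0_nm = numeric(), y0_nm = numeric(),
             x1_nm = numeric(), y1_nm = numeric(), d_nm = numeric(),
             lateral_nm = numeric(), sigma0_nm = numeric(),
             sigma1_nm = numeric(), sigma_excess_nm = numeric(),
             lambda_nm = numeric(), unc0_nm = numeric(), unc1_nm = numeric(),
             photons0 = numeric(), photons1 = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

#' Complete the spectral observables of linked pairs
#'
#' Fills the distance-derived columns of a pairs table: the projected
#' distance `d_nm` and lateral offset (recomputed from the stored positions
#' and the calibrated axis), the excess 1st-order width
#' `sqrt(max(0, sigma1^2 - sigma0^2))`, and the inferred mean emission
#' wavelength via [distance_to_wavelength()].
#'
#' @param pairs Pairs data frame (see [link_orders()]).
#' @param cal A [dispersion_calibration()].
#' @return The completed pairs data frame.
#' @export
pair_observables <- function(pairs, cal) {
  if (nrow(pairs) == 0) return(pairs)
  theta <- cal$axis_deg * pi / 180
  dx <- pairs$x1_nm - pairs$x0_nm
  dy <- pairs$y1_nm - pairs$y0_nm
  pairs$d_nm <- dx * cos(theta) + dy * sin(theta)
  pairs$lateral_nm <- -dx * sin(theta) + dy * cos(theta)
  pairs$sigma_excess_nm <-
    sqrt(pmax(0, pairs$sigma1_nm^2 - pairs$sigma0_nm^2))
  pairs$lambda_nm <- distance_to_wavelength(pairs$d_nm, cal)
  pairs
}

#' Histogram of 0th-to-1st-order distances
#'
#' Fixed-width, half-open bins `[lower, upper)` covering the observed
#' distance range.
#'
#' @param pairs Pairs data frame with a `d_nm` column (or a numeric vector
#'   of distances).
#' @param bin_nm Bin width (nm), > 0.
#' @return A data frame with `lower`, `upper`, `mid` (nm) and `count`;
#'   total count equals the number of pairs.
#' @export
pair_distance_histogram <- function(pairs, bin_nm = 5) {
  d <- if (is.data.frame(pairs)) pairs$d_nm else as.numeric(pairs)
  if (length(d) == 0) stop("no pairs to histogram")
  if (bin_nm <= 0) stop("bin width must be positive")
  lo <- floor(min(d) / bin_nm) * bin_nm
  breaks <- seq(lo, max(d) + bin_nm, by = bin_nm)
  counts <- tabulate(findInterval(d, breaks), nbins = length(breaks) - 1)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             mid = breaks[-length(breaks)] + bin_nm / 2, count = counts)
}

#' Group pairs into per-emitter traces by 0th-order position
#'
#' Cross-frame grouping for time-trace analysis: pairs whose 0th-order
#' positions fall within one PSF sigma of an existing group (greedy, in
#' frame order) are assigned the same `emitter_id`.
#'
#' @param pairs Pairs data frame.
#' @param radius_nm Grouping radius; one PSF sigma is a good default.
#' @return The pairs data frame with an `emitter_id` column, ordered by
#'   `emitter_id` then `frame`.
#' @export
group_pairs_by_position <- function(pairs, radius_nm = 150) {
  if (nrow(pairs) == 0) {
    pairs$emitter_id <- integer(0)
    return(pairs)
  }
  pairs <- pairs[order(pairs$frame), ]
  cx <- c(); cy <- c()
  ids <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (length(cx)) {
      d2 <- (cx - pairs$x0_nm[i])^2 + (cy - pairs$y0_nm[i])^2
      j <- which.min(d2)
      if (d2[j] <= radius_nm^2) {
        ids[i] <- j
        next
      }
    }
    cx <- c(cx, pairs$x0_nm[i]); cy <- c(cy, pairs$y0_nm[i])
    ids[i] <- length(cx)
  }
  pairs$emitter_id <- ids
  pairs[order(pairs$emitter_id, pairs$frame), ]
}
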