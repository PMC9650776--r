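#' A FRET state in (distance, width) observable space
#'
#' One 2D Gaussian component of the joint distribution of the
#' 0th-to-1st-order distance d and the raw 1st-order width sigma. Both
#' observables grow with FRET efficiency (the mixed emission moves red and
#' broadens), so donor-only, intermediate- and high-FRET populations occupy
#' ordered positions along both axes. A `background` state models sparse
#' nonsense linkages as a broad diffuse component and is excluded from
#' transition-event logic.
#'
#' @param name State name; by convention one of `donor_only`, `fret_low`,
#'   `fret_high`, `background` (free-form names are allowed).
#' @param mean `c(d_nm, sigma_nm)` center.
#' @param covariance Symmetric positive-definite 2x2 matrix (nm^2).
#' @param weight Non-negative mixing fraction.
#' @return An object of class `fret_state`.
#' @export
fret_state <- function(name, mean, covariance, weight = 1) {
  mean <- as.numeric(mean)
  if (length(mean) != 2) stop("mean must be c(d_nm, sigma_nm)")
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      any(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("covariance must be symmetric positive definite")
  if (weight < 0) stop("weight must be non-negative")
  structure(list(name = as.character(name)[1], mean = mean,
                 covariance = covariance, weight = weight),
            class = "fret_state")
}

#' @export
print.fret_state <- function(x, ...) {
  cat(sprintf("<fret_state> %s: mean (%.0f, %.0f) nm, sd (%.0f, %.0f) nm, w %.3f\n",
              x$name, x$mean[1], x$mean[2], sqrt(x$covariance[1, 1]),
              sqrt(x$covariance[2, 2]), x$weight))
  invisible(x)
}

# Bivariate normal density, closed form for a 2x2 covariance.
dmvnorm2 <- function(x, y, mean, cov) {
  det_ <- cov[1, 1] * cov[2, 2] - cov[1, 2]^2
  if (det_ <= 0) stop("singular covariance")
  dx <- x - mean[1]; dy <- y - mean[2]
  q <- (cov[2, 2] * dx^2 - 2 * cov[1, 2] * dx * dy + cov[1, 1] * dy^2) / det_
  exp(-q / 2) / (2 * pi * sqrt(det_))
}

#' Predict the (distance, width) observables at a given FRET efficiency
#'
#' Mixes the corrected donor and acceptor spectra at efficiency `E`
#' ([fret_mixed_spectrum()]), then maps the mixture's weighted mean
#' wavelength to a 0th-to-1st-order distance and its spectral width to the
#' 1st-order pattern width. Both observables are strictly increasing in `E`
#' when the acceptor emits redder than the donor, which is the basis of
#' distance/width FRET readout.
#'
#' @param efficiency FRET efficiency in \[0, 1\] (scalar or vector).
#' @param donor,acceptor Corrected [emission_spectrum()] objects.
#' @param config An [optical_config()].
#' @param cal A [dispersion_calibration()].
#' @return A data frame with columns `efficiency`, `d_nm`, `sigma_nm`.
#' @export
predict_fret_observables <- function(efficiency, donor, acceptor, config,
                                     cal) {
  out <- lapply(efficiency, function(E) {
    mix <- fret_mixed_spectrum(donor, acceptor, E)
    data.frame(efficiency = E,
               d_nm = wavelength_to_distance(weighted_mean_wavelength(mix),
                                             cal),
               sigma_nm = predicted_first_order_width(mix, config, cal))
  })
  do.call(rbind, out)
}

#' Fit 2D Gaussian states to the (distance, width) histogram
#'
#' Bins the `(d, sigma)` observations of a pairs table into a 2D histogram
#' and fits it with a sum of axis-aligned 2D Gaussian profiles (one per
#' initial state) by maximizing the Poisson likelihood of the bin counts
#' (bin-integrated model, so bin width does not bias the centers). Initial
#' states — typically donor-only, one or two FRET
#' states, and a broad low-amplitude background — must be supplied with
#' distinct means. Degenerate fitted widths are floored at half a bin and
#' flagged.
#'
#' @param pairs Pairs data frame with `d_nm` and `sigma1_nm` columns (or a
#'   data frame with `d_nm`, `sigma_nm`).
#' @param init List of [fret_state()] objects (length = number of states).
#' @param bin_nm `c(d_bin, sigma_bin)` histogram bin widths (nm).
#' @return A list of fitted `fret_state` objects (weights normalized to 1),
#'   with attributes `se` (per-state matrix of standard errors: d, sigma of
#'   center), `rss`, and `flagged` (states whose width hit the floor).
#' @export
fit_dsigma_histogram <- function(pairs, init, bin_nm = c(10, 10)) {
  d <- pairs$d_nm
  s <- if (!is.null(pairs$sigma1_nm)) pairs$sigma1_nm else pairs$sigma_nm
  if (length(d) < 50 * length(init))
    warning("fewer than 50 observations per state; fit may be unstable")
  means <- t(vapply(init, function(st) st$mean, numeric(2)))
  if (anyDuplicated(round(means)) > 0)
    stop("initial state means must be distinct")
  n_states <- length(init)
  bd <- bin_nm[1]; bs <- bin_nm[2]
  dlo <- floor(min(d) / bd) * bd
  slo <- floor(min(s) / bs) * bs
  dbreaks <- seq(dlo, max(d) + bd, by = bd)
  sbreaks <- seq(slo, max(s) + bs, by = bs)
  nd <- length(dbreaks) - 1L; ns <- length(sbreaks) - 1L
  id <- findInterval(d, dbreaks); is_ <- findInterval(s, sbreaks)
  counts <- matrix(0, ns, nd)
  for (i in seq_along(d)) counts[is_[i], id[i]] <- counts[is_[i], id[i]] + 1
  counts <- as.numeric(counts)

  # per state: (md, ms, log sd_d, log sd_s, log amp)
  par0 <- unlist(lapply(init, function(st)
    c(st$mean, log(sqrt(st$covariance[1, 1])),
      log(sqrt(st$covariance[2, 2])),
      log(max(st$weight, 1e-3) * length(d)))))
  predict_counts <- function(p) {
    out <- numeric(nd * ns)
    for (k in seq_len(n_states)) {
      q <- p[(5 * k - 4):(5 * k)]
      px <- stats::pnorm(dbreaks, q[1], exp(q[3]))
      py <- stats::pnorm(sbreaks, q[2], exp(q[4]))
      out <- out + exp(q[5]) *
        as.numeric(outer(diff(py), diff(px)))
    }
    out
  }
  parscale <- rep(c(5, 5, 0.05, 0.05, 0.05), n_states)
  fit <- hist_fit(par0, predict_counts, counts, maxit = 2000,
                  parscale = parscale)
  if (fit$convergence != 0)
    stop("2D state fit did not converge (optim code ", fit$convergence, ")")
  se <- sqrt(pmax(diag(fit$cov), 0))
  amps <- exp(fit$par[5 * seq_len(n_states)])
  flagged <- character(0)
  states <- lapply(seq_len(n_states), function(k) {
    q <- fit$par[(5 * k - 4):(5 * k)]
    sd_d <- exp(q[3]); sd_s <- exp(q[4])
    floor_ <- c(bd, bs) / 2
    if (sd_d < floor_[1] || sd_s < floor_[2]) {
      flagged <<- c(flagged, init[[k]]$name)
      sd_d <- max(sd_d, floor_[1]); sd_s <- max(sd_s, floor_[2])
    }
    fret_state(init[[k]]$name, mean = q[1:2],
               covariance = diag(c(sd_d^2, sd_s^2)),
               weight = amps[k] / sum(amps))
  })
  se_mat <- t(vapply(seq_len(n_states), function(k)
    se[(5 * k - 4):(5 * k - 3)], numeric(2)))
  colnames(se_mat) <- c("d_se", "sigma_se")
  rownames(se_mat) <- vapply(init, function(st) st$name, character(1))
  attr(states, "se") <- se_mat
  attr(states, "rss") <- fit$rss
  attr(states, "flagged") <- flagged
  states
}

#' Posterior state probabilities for one (distance, width) observation
#'
#' Posterior proportional to `weight x bivariate normal density` at
#' `(d, sigma)`, normalized over the supplied states. Exact ties are broken
#' toward the `donor_only` state if present, else toward the first state in
#' the list.
#'
#' @param d_nm,sigma_nm Observed distance and 1st-order width (nm); vectors
#'   of equal length are accepted.
#' @param states List of [fret_state()] objects.
#' @return A list with `posterior` (matrix, one row per observation, one
#'   column per state) and `state` (character vector of most-likely state
#'   names).
#' @export
state_likelihoods <- function(d_nm, sigma_nm, states) {
  if (length(states) == 0) stop("states must be non-empty")
  names_ <- vapply(states, function(s) s$name, character(1))
  dens <- vapply(states, function(st)
    st$weight * dmvnorm2(d_nm, sigma_nm, st$mean, st$covariance),
    numeric(length(d_nm)))
  dens <- matrix(dens, nrow = length(d_nm))
  colnames(dens) <- names_
  # tie-break order: donor_only first, then original order
  pref <- order(names_ != "donor_only")
  post <- dens / rowSums(dens)
  pick <- apply(post[, pref, drop = FALSE], 1, which.max)
  list(posterior = post, state = names_[pref][pick])
}

#' Assign per-frame states and detect bleach/blink events in a trace
#'
#' Computes the most-likely state of every frame of one emitter's trace
#' (per-frame independent calls; no temporal smoothing) and scans the state
#' sequence for acceptor photophysics: a FRET state falling back to
#' `donor_only` with no later return to FRET is a *bleach*; FRET ->
#' donor-only -> FRET is a *blink*. A state change only counts once the new
#' state persists for at least `min_dwell` consecutive observed frames,
#' which suppresses single-frame classification flips; `background` calls
#' are ignored by the event logic.
#'
#' @param trace Data frame with `frame`, `d_nm` and `sigma_nm` (or
#'   `sigma1_nm`) for one emitter, in any frame order.
#' @param states List of [fret_state()] objects (fitted).
#' @param min_dwell Minimum consecutive frames to accept a state change.
#' @return An object of class `state_trace`: list with `frames` (data frame
#'   `frame`, `d_nm`, `sigma_nm`, `state`, and one posterior column
#'   `p_<state>` per state) and `events` (data frame `type`, `frame` where
#'   `type` is `bleach` or `blink` and `frame` is the first donor-only frame
#'   of the event).
#' @export
trace_states <- function(trace, states, min_dwell = 2) {
  if (nrow(trace) == 0) stop("empty trace")
  trace <- trace[order(trace$frame), ]
  s <- if (!is.null(trace$sigma_nm)) trace$sigma_nm else trace$sigma1_nm
  lik <- state_likelihoods(trace$d_nm, s, states)
  frames <- data.frame(frame = trace$frame, d_nm = trace$d_nm, sigma_nm = s,
                       state = lik$state, stringsAsFactors = FALSE)
  for (j in colnames(lik$posterior))
    frames[[paste0("p_", j)]] <- lik$posterior[, j]

  seq_ <- frames$state[frames$state != "background"]
  fr_ <- frames$frame[frames$state != "background"]
  events <- data.frame(type = character(), frame = integer(),
                       stringsAsFactors = FALSE)
  if (length(seq_) > 0) {
    r <- rle(seq_)
    keep <- r$lengths >= min_dwell
    runs <- data.frame(state = r$values[keep],
                       start = cumsum(c(1, r$lengths))[-(length(r$lengths) + 1)][keep])
    if (nrow(runs) > 1) {
      r2 <- rle(runs$state)  # collapse adjacent equal runs split by short flickers
      starts <- runs$start[cumsum(c(1, r2$lengths))[-(length(r2$lengths) + 1)]]
      st <- r2$values
      is_fret <- st != "donor_only"
      for (i in seq_along(st)) {
        if (i == 1 || st[i] != "donor_only" || !is_fret[i - 1]) next
        later_fret <- any(is_fret[seq_along(st) > i])
        events <- rbind(events, data.frame(
          type = if (later_fret) "blink" else "bleach",
          frame = fr_[starts[i]], stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(frames = frames, events = events), class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d frames, states: %s; %d event(s)\n",
              nrow(x$frames),
              paste(unique(x$frames$state), collapse = ", "),
              nrow(x$events)))
  if (nrow(x$events))
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  %s at frame %d\n", x$events$type[i], x$events$frame[i]))
  invisible(x)
}
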