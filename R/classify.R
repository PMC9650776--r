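#' Fit a sum of Gaussian populations to a distance histogram
#'
#' Fits `n_components` Gaussian curves to the binned 0th-to-1st-order
#' distance counts by maximizing the Poisson likelihood of the bin counts
#' (the Poisson-weighted refinement of a least-squares histogram fit; the
#' bin model integrates each Gaussian over the bin, so results are unbiased
#' by the bin width). Components listed
#' in `frozen` keep their mean and sigma fixed and only fit their amplitude —
#' the device used to fit a second population "on top of" an
#' already-characterized first one. Parameter uncertainties are reported as
#' standard errors and 95% confidence intervals from the Gauss-Newton
#' covariance at the optimum.
#'
#' @param histogram Output of [pair_distance_histogram()] (columns `lower`,
#'   `upper`, `mid`, `count`).
#' @param n_components Number of free Gaussian components, >= 1.
#' @param init Optional data frame / list with `mean`, `sigma`, `amplitude`
#'   (amplitude = total count of the component) for the free components.
#'   Defaults to quantile-spread means over the occupied range.
#' @param frozen Optional `mixture_model_1d` whose components are added with
#'   fixed (mean, sigma) and free amplitude.
#' @return An object of class `mixture_model_1d`: list with `components`
#'   (data frame: `mean`, `sigma`, `amplitude`, `mean_se`, `sigma_se`,
#'   `amplitude_se`, `mean_ci95`, `sigma_ci95`, `frozen`), `rss`,
#'   `bin_nm`.
#' @export
fit_distance_histogram <- function(histogram, n_components, init = NULL,
                                   frozen = NULL) {
  h <- as.data.frame(histogram)
  if (nrow(h) == 0 || sum(h$count) == 0) stop("histogram is empty")
  occupied <- sum(h$count > 0)
  if (n_components < 1) stop("need at least one component")
  if (3 * n_components > occupied + 2)
    stop("n_components (", n_components,
         ") exceeds the support of the histogram (", occupied,
         " occupied bins)")
  total <- sum(h$count)
  if (is.null(init)) {
    # 1D k-means on the binned sample: robust to strongly overlapping
    # populations, deterministic (quantile start)
    xs <- rep(h$mid, h$count)
    qs <- as.numeric(stats::quantile(xs, probs = (seq_len(n_components) - 0.5) /
                                       n_components))
    if (n_components > 1) {
      for (it in 1:25) {
        grp <- apply(abs(outer(xs, qs, "-")), 1, which.min)
        qs_new <- vapply(seq_len(n_components), function(k)
          if (any(grp == k)) mean(xs[grp == k]) else qs[k], numeric(1))
        if (max(abs(qs_new - qs)) < 1e-6) break
        qs <- qs_new
      }
      grp <- apply(abs(outer(xs, qs, "-")), 1, which.min)
      sig <- vapply(seq_len(n_components), function(k)
        max(stats::sd(xs[grp == k]), h$upper[1] - h$lower[1]), numeric(1))
      amp <- vapply(seq_len(n_components), function(k)
        max(sum(grp == k), 1), numeric(1))
      init <- list(mean = qs, sigma = sig, amplitude = amp)
    } else {
      init <- list(mean = qs, sigma = stats::sd(xs), amplitude = total)
    }
  }
  init <- as.data.frame(init)
  if (any(init$mean < min(h$lower) | init$mean > max(h$upper)))
    stop("initial means must lie inside the histogram range")

  frozen_comp <- if (!is.null(frozen)) frozen$components else NULL
  n_frozen <- if (is.null(frozen_comp)) 0L else nrow(frozen_comp)

  # free components: (mean, log sigma, log amp); frozen: (log amp)
  par0 <- c(rbind(init$mean, log(init$sigma), log(init$amplitude)))
  if (n_frozen > 0)
    par0 <- c(par0, log(pmax(frozen_comp$amplitude, 1)))

  predict_counts <- function(p) {
    out <- numeric(nrow(h))
    for (k in seq_len(n_components)) {
      m <- p[3 * k - 2]; s <- exp(p[3 * k - 1]); a <- exp(p[3 * k])
      out <- out + a * (stats::pnorm(h$upper, m, s) -
                          stats::pnorm(h$lower, m, s))
    }
    for (k in seq_len(n_frozen)) {
      a <- exp(p[3 * n_components + k])
      out <- out + a * (stats::pnorm(h$upper, frozen_comp$mean[k],
                                     frozen_comp$sigma[k]) -
                          stats::pnorm(h$lower, frozen_comp$mean[k],
                                       frozen_comp$sigma[k]))
    }
    out
  }
  parscale <- c(rep(c(5, 0.05, 0.05), n_components),
                rep(0.05, n_frozen))
  fit <- hist_fit(par0, predict_counts, h$count, parscale = parscale)
  if (fit$convergence != 0)
    stop("mixture fit did not converge (optim code ", fit$convergence,
         ", rss ", signif(fit$rss, 4), ")")
  se <- sqrt(pmax(diag(fit$cov), 0))
  comp <- do.call(rbind, lapply(seq_len(n_components), function(k) {
    s <- exp(fit$par[3 * k - 1]); a <- exp(fit$par[3 * k])
    data.frame(mean = fit$par[3 * k - 2], sigma = s, amplitude = a,
               mean_se = se[3 * k - 2], sigma_se = se_exp(s, se[3 * k - 1]),
               amplitude_se = se_exp(a, se[3 * k]), frozen = FALSE)
  }))
  if (n_frozen > 0) {
    compf <- do.call(rbind, lapply(seq_len(n_frozen), function(k) {
      a <- exp(fit$par[3 * n_components + k])
      data.frame(mean = frozen_comp$mean[k], sigma = frozen_comp$sigma[k],
                 amplitude = a, mean_se = 0, sigma_se = 0,
                 amplitude_se = se_exp(a, se[3 * n_components + k]),
                 frozen = TRUE)
    }))
    comp <- rbind(comp, compf)
  }
  comp <- comp[order(comp$mean), ]
  rownames(comp) <- NULL
  comp$mean_ci95 <- 1.96 * comp$mean_se
  comp$sigma_ci95 <- 1.96 * comp$sigma_se
  structure(list(components = comp, rss = fit$rss,
                 bin_nm = h$upper[1] - h$lower[1]),
            class = "mixture_model_1d")
}

#' @export
print.mixture_model_1d <- function(x, ...) {
  cat("<mixture_model_1d>\n")
  for (i in seq_len(nrow(x$components))) {
    c_ <- x$components[i, ]
    cat(sprintf("  %s mean %.1f +/- %.1f nm, sigma %.1f +/- %.1f nm, n ~ %.0f\n",
                if (c_$frozen) "[frozen]" else "        ",
                c_$mean, c_$mean_ci95, c_$sigma, c_$sigma_ci95, c_$amplitude))
  }
  invisible(x)
}

#' Assign a fluorophore species label to each spectral pair
#'
#' Either a hard distance cutoff (`rule = "threshold"`; a pair exactly at the
#' cutoff gets the upper label) or maximum likelihood under a fitted
#' [fit_distance_histogram()] model (`rule = "max_likelihood"`: the component
#' with the highest amplitude-weighted Gaussian density at the pair's
#' distance wins; ties go to the smaller-mean component).
#'
#' @param pairs Pairs data frame with a `d_nm` column.
#' @param rule `"threshold"` or `"max_likelihood"`.
#' @param cutoff_nm Distance cutoff for the threshold rule (e.g. 3054 nm to
#'   separate ATTO647N from ATTO655 on the default instrument).
#' @param model A `mixture_model_1d` for the max-likelihood rule.
#' @param labels Character labels; for the threshold rule, `labels[1]` is
#'   the short-distance species. For the max-likelihood rule, one label per
#'   model component (defaults to `comp1`, `comp2`, ...).
#' @return The pairs data frame with `label` filled in.
#' @export
assign_species <- function(pairs, rule = c("threshold", "max_likelihood"),
                           cutoff_nm = NULL, model = NULL, labels = NULL) {
  rule <- match.arg(rule)
  if (nrow(pairs) == 0) return(pairs)
  if (rule == "threshold") {
    if (is.null(cutoff_nm)) stop("threshold rule needs cutoff_nm")
    if (is.null(labels)) labels <- c("A", "B")
    pairs$label <- ifelse(pairs$d_nm < cutoff_nm, labels[1], labels[2])
  } else {
    if (is.null(model)) stop("max_likelihood rule needs a fitted model")
    comp <- model$components
    if (is.null(labels)) labels <- paste0("comp", seq_len(nrow(comp)))
    dens <- vapply(seq_len(nrow(comp)), function(k)
      comp$amplitude[k] * stats::dnorm(pairs$d_nm, comp$mean[k],
                                       comp$sigma[k]),
      numeric(nrow(pairs)))
    dens <- matrix(dens, nrow = nrow(pairs))
    pairs$label <- labels[apply(dens, 1, which.max)]  # first max: smaller mean
  }
  pairs
}

#' Render a pseudocolored localization map
#'
#' Bins the 0th-order positions of the pairs onto a pixel grid and colors
#' each occupied pixel either by the mean 0th-to-1st-order distance
#' (`color_by = "d"`, continuous colormap between `limits`) or by the
#' majority species label (`color_by = "label"`).
#'
#' @param pairs Pairs data frame.
#' @param extent `c(width_nm, height_nm)` of the rendered area (origin at 0).
#' @param px_nm Rendering pixel size (nm), > 0.
#' @param color_by `"d"` or `"label"`.
#' @param limits Distance limits for the colormap (defaults to the data
#'   range).
#' @param palette Colormap name passed to [grDevices::hcl.colors()].
#' @return A list with `rgb` (array `[ny, nx, 3]` in \[0, 1\]), `counts`
#'   (localizations per pixel) and `value` (per-pixel mean distance or label
#'   index, NA where empty).
#' @export
render_map <- function(pairs, extent, px_nm, color_by = c("d", "label"),
                       limits = NULL, palette = "Viridis") {
  color_by <- match.arg(color_by)
  if (px_nm <= 0) stop("px_nm must be positive")
  nx <- max(1L, ceiling(extent[1] / px_nm))
  ny <- max(1L, ceiling(extent[2] / px_nm))
  counts <- matrix(0L, ny, nx)
  value <- matrix(NA_real_, ny, nx)
  rgb_arr <- array(0, c(ny, nx, 3))
  if (nrow(pairs) > 0) {
    ix <- floor(pairs$x0_nm / px_nm) + 1L
    iy <- floor(pairs$y0_nm / px_nm) + 1L
    keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    ix <- ix[keep]; iy <- iy[keep]
    if (color_by == "d") {
      v <- pairs$d_nm[keep]
    } else {
      if (all(is.na(pairs$label))) stop("pairs have no labels to render")
      v <- as.numeric(factor(pairs$label[keep]))
    }
    for (i in seq_along(ix)) {
      counts[iy[i], ix[i]] <- counts[iy[i], ix[i]] + 1L
      value[iy[i], ix[i]] <- if (is.na(value[iy[i], ix[i]]))
        v[i] else value[iy[i], ix[i]] + v[i]
    }
    value <- value / ifelse(counts > 0, counts, 1)
    n_col <- 256L
    cols <- grDevices::hcl.colors(n_col, palette)
    if (is.null(limits)) limits <- range(v)
    span <- max(limits[2] - limits[1], .Machine$double.eps)
    occ <- which(counts > 0)
    idx <- pmin(pmax(round((value[occ] - limits[1]) / span * (n_col - 1)) + 1,
                     1), n_col)
    channels <- grDevices::col2rgb(cols[idx]) / 255
    for (ch in 1:3) {
      plane <- rgb_arr[, , ch]
      plane[occ] <- channels[ch, ]
      rgb_arr[, , ch] <- plane
    }
  }
  list(rgb = rgb_arr, counts = counts, value = value)
}
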