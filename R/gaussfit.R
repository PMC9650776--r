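# Shared machinery for sums-of-Gaussians histogram fits.
#
# Bin counts are Poisson distributed (var = mu), so the fits maximize the
# Poisson likelihood of the binned counts rather than minimizing an
# unweighted sum of squares: plain least squares is the mu -> large limit of
# the same estimator but showed bias exceeding its own confidence intervals
# for strongly overlapping components. Optimization is BFGS with a
# Nelder-Mead polish (and a second BFGS pass) to escape shallow stalls.
# The covariance is the inverse Fisher information (J' diag(1/mu) J)^-1 at
# the optimum, pseudo-inverted so that near-degenerate directions (e.g. a
# vanishing background amplitude) yield large-but-finite variances.

hist_fit <- function(par0, predict_counts, counts, maxit = 2000,
                     parscale = NULL) {
  nll <- function(p) {
    mu <- pmax(predict_counts(p), 1e-12)
    sum(mu) - sum(counts * log(mu))
  }
  ctrl <- list(maxit = maxit, reltol = 1e-12)
  if (!is.null(parscale)) ctrl$parscale <- parscale
  fit <- stats::optim(par0, nll, method = "BFGS", control = ctrl)
  fit2 <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 3000))
  if (fit2$value < fit$value) fit <- fit2
  fit3 <- stats::optim(fit$par, nll, method = "BFGS", control = ctrl)
  if (fit3$value < fit$value) fit <- fit3
  if (!all(is.finite(fit$par)))
    stop("mixture fit diverged (non-finite parameters)")
  p <- fit$par
  mu <- pmax(predict_counts(p), 1e-12)
  eps <- pmax(abs(p), 1e-3) * 1e-5
  J <- vapply(seq_along(p), function(k) {
    ph <- p; ph[k] <- ph[k] + eps[k]
    pl <- p; pl[k] <- pl[k] - eps[k]
    (predict_counts(ph) - predict_counts(pl)) / (2 * eps[k])
  }, numeric(length(mu)))
  sv <- svd(crossprod(J / sqrt(mu)))
  pos <- sv$d > max(sv$d) * 1e-12
  cov <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  list(par = p, cov = cov, rss = sum((mu - counts)^2),
       deviance = 2 * (nll(p) + sum(counts * log(pmax(counts, 1)) - counts)),
       convergence = fit$convergence, fitted = mu)
}

# Delta-method standard error for exp(p) given SE of p.
se_exp <- function(value, se_log) value * se_log
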