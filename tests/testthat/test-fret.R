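cfg <- optical_config()
cal <- default_calibration()

test_that("fret_state validates its covariance", {
  expect_error(fret_state("x", c(1, 2), matrix(c(1, 2, 2, 1), 2)), "definite")
  expect_error(fret_state("x", c(1, 2), diag(2), weight = -1), "negative")
  s <- fret_state("donor_only", c(2620, 172), diag(c(35^2, 30^2)), 0.4)
  expect_s3_class(s, "fret_state")
})

test_that("predicted observables are ordered and monotone in efficiency", {
  donor <- gaussian_spectrum(575, 25, qy = 0.8)
  acceptor <- gaussian_spectrum(665, 20, qy = 0.65)
  obs <- predict_fret_observables(c(0, 0.15, 0.55), donor, acceptor, cfg, cal)
  expect_true(all(diff(obs$d_nm) > 0))
  expect_true(all(diff(obs$sigma_nm) > 0))
  d0 <- predict_fret_observables(0, donor, acceptor, cfg, cal)
  expect_equal(d0$d_nm,
               wavelength_to_distance(weighted_mean_wavelength(donor), cal))

  grid <- predict_fret_observables(seq(0, 1, by = 0.1), donor, acceptor,
                                   cfg, cal)
  expect_true(all(diff(grid$d_nm) > 0))
})

test_that("ordering holds across synthetic spectra sets (property)", {
  set.seed(71)
  for (i in 1:6) {
    dm <- runif(1, 540, 600); am <- dm + runif(1, 60, 130)
    donor <- gaussian_spectrum(dm, runif(1, 18, 30), qy = runif(1, 0.5, 0.9))
    acceptor <- gaussian_spectrum(am, runif(1, 15, 25), qy = runif(1, 0.3, 0.8))
    obs <- predict_fret_observables(c(0, 0.15, 0.55), donor, acceptor, cfg,
                                    cal)
    expect_true(all(diff(obs$d_nm) > 0))
    expect_true(all(diff(obs$sigma_nm) > 0))
  }
})

test_that("posteriors equal the closed-form bivariate density and sum to one", {
  states <- reference_fret_states()
  set.seed(72)
  d <- runif(20, 2500, 2900); s <- runif(20, 120, 280)
  lik <- state_likelihoods(d, s, states)
  expect_equal(rowSums(lik$posterior), rep(1, 20), tolerance = 1e-12)
  for (i in c(1, 7, 20)) {
    dens <- vapply(states, function(st)
      st$weight * oracle_dmvnorm(c(d[i], s[i]), st$mean, st$covariance),
      numeric(1))
    expect_equal(unname(lik$posterior[i, ]), dens / sum(dens),
                 tolerance = 1e-12)
  }
})

test_that("observations at a state mean pick that state; ties go to donor_only", {
  eq_cov <- diag(c(30^2, 30^2))
  states <- list(fret_state("donor_only", c(2620, 172), eq_cov, 0.5),
                 fret_state("fret_high", c(2780, 172), eq_cov, 0.5))
  at_mean <- state_likelihoods(2780, 172, states)
  expect_equal(at_mean$state, "fret_high")
  midpoint <- state_likelihoods(2700, 172, states)
  expect_equal(midpoint$state, "donor_only")
  bad <- fret_state("x", c(0, 0), diag(c(1e-300, 1e-300)), 1)
  expect_error(state_likelihoods(1, 1, list(bad)), "singular")
})

test_that("2D state fit recovers the reference centers", {
  set.seed(73)
  st <- reference_fret_states()
  n <- 2000
  dat <- do.call(rbind, lapply(st[1:3], function(s) data.frame(
    d_nm = rnorm(n, s$mean[1], sqrt(s$covariance[1, 1])),
    sigma_nm = rnorm(n, s$mean[2], sqrt(s$covariance[2, 2])))))
  dat <- rbind(dat, data.frame(d_nm = rnorm(180, 2700, 200),
                               sigma_nm = rnorm(180, 205, 120)))
  init <- reference_fret_states()
  for (i in 1:3) init[[i]]$mean <- init[[i]]$mean + c(15, -12)
  fit <- fit_dsigma_histogram(dat, init)
  truth <- rbind(c(2620, 172), c(2653, 204), c(2781, 238))
  est <- t(vapply(fit[1:3], function(s) s$mean, numeric(2)))
  se <- attr(fit, "se")[1:3, ]
  expect_true(all(abs(est - truth) < 3.5 * se))
  expect_equal(sum(vapply(fit, function(s) s$weight, numeric(1))), 1)

  # single state: moments match the sample
  one <- fit_dsigma_histogram(dat[1:n, ],
                              list(fret_state("donor_only", c(2600, 180),
                                              diag(c(40^2, 40^2)))))
  expect_equal(one[[1]]$mean[1], mean(dat$d_nm[1:n]), tolerance = 1e-3)
  expect_equal(sqrt(one[[1]]$covariance[1, 1]), sd(dat$d_nm[1:n]),
               tolerance = 0.03)
})

test_that("2D fit is stable under half-bin origin shifts", {
  set.seed(74)
  st <- reference_fret_states()[c(1, 3)]
  n <- 1500
  dat <- do.call(rbind, lapply(st, function(s) data.frame(
    d_nm = rnorm(n, s$mean[1], sqrt(s$covariance[1, 1])),
    sigma_nm = rnorm(n, s$mean[2], sqrt(s$covariance[2, 2])))))
  f1 <- fit_dsigma_histogram(dat, st)
  dat2 <- dat
  dat2$d_nm <- dat2$d_nm + 5  # half of the 10 nm bin
  f2 <- fit_dsigma_histogram(dat2, st)
  for (k in 1:2) {
    shift <- f2[[k]]$mean - f1[[k]]$mean - c(5, 0)
    se <- attr(f1, "se")[k, ] + attr(f2, "se")[k, ]
    expect_true(all(abs(shift) < 3 * se + 0.5))
  }
})

test_that("traces detect bleaching and blinking at the right frames", {
  states <- reference_fret_states()
  mk <- function(seq_states, jitter = 5, seed = 75) {
    set.seed(seed)
    centers <- t(vapply(seq_states, function(nm) {
      st <- states[[which(vapply(states, function(s) s$name, character(1)) == nm)]]
      st$mean
    }, numeric(2)))
    data.frame(frame = seq_along(seq_states),
               d_nm = centers[, 1] + rnorm(length(seq_states), 0, jitter),
               sigma_nm = centers[, 2] + rnorm(length(seq_states), 0, jitter))
  }
  flat <- trace_states(mk(rep("fret_high", 12)), states)
  expect_equal(unique(flat$frames$state), "fret_high")
  expect_equal(nrow(flat$events), 0)

  bleach <- trace_states(mk(c(rep("fret_high", 8), rep("donor_only", 8))),
                         states)
  expect_equal(bleach$events$type, "bleach")
  expect_lte(abs(bleach$events$frame - 9), 1)

  blink <- trace_states(mk(c(rep("fret_high", 6), rep("donor_only", 4),
                             rep("fret_high", 6))), states)
  expect_equal(blink$events$type, "blink")
  expect_lte(abs(blink$events$frame - 7), 1)

  expect_error(trace_states(data.frame(frame = integer(), d_nm = numeric(),
                                       sigma_nm = numeric()), states),
               "empty")
})

test_that("15%-state misclassification tracks the analytic overlap", {
  states <- reference_fret_states(include_background = FALSE)
  set.seed(76)
  n <- 4e3
  d <- rnorm(n, states[[2]]$mean[1], sqrt(states[[2]]$covariance[1, 1]))
  s <- rnorm(n, states[[2]]$mean[2], sqrt(states[[2]]$covariance[2, 2]))
  lik <- state_likelihoods(d, s, states)
  mis <- mean(lik$state != "fret_low")
  # analytic misclassification of the fret_low state by Monte Carlo density
  # comparison on an independent fine sample
  m <- 2e5
  dd <- rnorm(m, states[[2]]$mean[1], sqrt(states[[2]]$covariance[1, 1]))
  ss <- rnorm(m, states[[2]]$mean[2], sqrt(states[[2]]$covariance[2, 2]))
  dens <- vapply(states, function(st)
    st$weight * dmvnorm_vec(dd, ss, st$mean, st$covariance),
    numeric(m))
  mis_true <- mean(max.col(dens) != 2)
  expect_gt(mis, 0.05)  # genuinely overlapping: degradation is expected
  expect_lt(abs(mis - mis_true), 0.03)
})
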