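test_that("a single population is recovered at the printed parameters", {
  set.seed(101)
  d <- rnorm(1e4, 3014, 34)
  m <- fit_distance_histogram(pair_distance_histogram(d, 5), 1)
  comp <- m$components
  expect_lt(abs(comp$mean - 3014), 3 * comp$mean_se)
  expect_equal(comp$sigma, 34, tolerance = 0.05)
  expect_equal(comp$amplitude, 1e4, tolerance = 0.05)
})

test_that("two separated populations are recovered by a free two-component fit", {
  set.seed(102)
  d <- c(rnorm(6e3, 3014, 34), rnorm(4e3, 3090, 41))
  m <- fit_distance_histogram(pair_distance_histogram(d, 5), 2)
  comp <- m$components
  expect_lt(abs(comp$mean[1] - 3014), 3 * comp$mean_se[1])
  expect_lt(abs(comp$mean[2] - 3090), 3 * comp$mean_se[2])
  se_diff <- sqrt(comp$mean_se[1]^2 + comp$mean_se[2]^2)
  expect_lt(abs((comp$mean[2] - comp$mean[1]) - 76), 3 * se_diff)
})

test_that("freezing the first component reproduces the free fit's second mean", {
  set.seed(103)
  d <- c(rnorm(6e3, 3014, 34), rnorm(4e3, 3090, 41))
  h <- pair_distance_histogram(d, 5)
  free <- fit_distance_histogram(h, 2)
  # the first population characterized on its own (separate acquisition)
  frozen_base <- fit_distance_histogram(
    pair_distance_histogram(rnorm(6e3, 3014, 34), 5), 1)
  comb <- fit_distance_histogram(h, 1,
                                 init = list(mean = 3085, sigma = 45,
                                             amplitude = 4000),
                                 frozen = frozen_base)
  free_second <- free$components$mean[2]
  comb_second <- comb$components$mean[!comb$components$frozen]
  expect_lt(abs(comb_second - free_second),
            comb$components$mean_ci95[!comb$components$frozen] +
              free$components$mean_ci95[2])
})

test_that("histogram fit validates inputs and errors usefully", {
  set.seed(104)
  h <- pair_distance_histogram(rnorm(50, 3000, 10), 5)
  expect_error(fit_distance_histogram(h, 20), "support")
  expect_error(fit_distance_histogram(h, 1, init = list(mean = 5000,
                                                        sigma = 10,
                                                        amplitude = 10)),
               "inside")
  expect_error(fit_distance_histogram(data.frame(lower = 1, upper = 2,
                                                 mid = 1.5, count = 0), 1),
               "empty")
})

test_that("threshold species assignment uses the documented tie rule", {
  pairs <- data.frame(d_nm = c(3014, 3090, 3054))
  out <- assign_species(pairs, "threshold", cutoff_nm = 3054,
                        labels = c("ATTO647N", "ATTO655"))
  expect_equal(out$label, c("ATTO647N", "ATTO655", "ATTO655"))
})

test_that("max-likelihood assignment matches the analytic Bayes rule", {
  set.seed(105)
  n <- 2e4
  truth <- rep(c("A", "B"), each = n / 2)
  d <- c(rnorm(n / 2, 3077, 56), rnorm(n / 2, 3128, 62))
  model <- structure(list(components = data.frame(
    mean = c(3077, 3128), sigma = c(56, 62), amplitude = c(n / 2, n / 2))),
    class = "mixture_model_1d")
  out <- assign_species(data.frame(d_nm = d), "max_likelihood",
                        model = model, labels = c("A", "B"))
  err_rate <- mean(out$label != truth)
  # analytic Bayes error of the two-Gaussian mixture by dense quadrature
  x <- seq(2700, 3500, by = 0.25)
  fa <- 0.5 * dnorm(x, 3077, 56); fb <- 0.5 * dnorm(x, 3128, 62)
  bayes <- oracle_trapz(x, pmin(fa, fb))
  expect_lt(abs(err_rate - bayes), 0.02)
})

test_that("cutoff classification at the printed boundary separates the dyes", {
  set.seed(106)
  d <- c(rnorm(3e3, 3014, 34), rnorm(3e3, 3090, 41))
  truth <- rep(c("ATTO647N", "ATTO655"), each = 3e3)
  out <- assign_species(data.frame(d_nm = d), "threshold", cutoff_nm = 3054,
                        labels = c("ATTO647N", "ATTO655"))
  x <- seq(2850, 3300, by = 0.25)
  bayes_cutoff <- oracle_trapz(x, pmin(0.5 * dnorm(x, 3014, 34),
                                       0.5 * dnorm(x, 3090, 41)))
  expect_lt(abs(mean(out$label != truth) - bayes_cutoff), 0.02)
})

test_that("mixture fit is a fixed point of its own generative model", {
  set.seed(107)
  m0 <- data.frame(mean = c(3014, 3090), sigma = c(34, 41),
                   amplitude = c(5e3, 5e3))
  d <- c(rnorm(m0$amplitude[1], m0$mean[1], m0$sigma[1]),
         rnorm(m0$amplitude[2], m0$mean[2], m0$sigma[2]))
  fit <- fit_distance_histogram(pair_distance_histogram(d, 5), 2)
  comp <- fit$components
  expect_lt(abs(comp$mean[1] - m0$mean[1]), comp$mean_ci95[1] * 1.6)
  expect_lt(abs(comp$mean[2] - m0$mean[2]), comp$mean_ci95[2] * 1.6)
  expect_lt(abs(comp$sigma[1] - m0$sigma[1]), comp$sigma_ci95[1] * 1.6)
})

test_that("render_map colors pixels by distance or label", {
  blank <- render_map(empty_pairs_df(), c(1000, 1000), 100)
  expect_equal(dim(blank$rgb), c(10, 10, 3))
  expect_true(all(blank$rgb == 0))

  pairs <- data.frame(x0_nm = c(150, 850), y0_nm = c(150, 850),
                      d_nm = c(3014, 3090),
                      label = c("A", "B"))
  img <- render_map(pairs, c(1000, 1000), 100, color_by = "d")
  expect_equal(sum(img$counts), 2)
  expect_equal(img$counts[2, 2], 1)
  expect_equal(img$value[2, 2], 3014)
  # two species at distinct d get distinct colors
  c1 <- img$rgb[2, 2, ]; c2 <- img$rgb[9, 9, ]
  expect_gt(sum(abs(c1 - c2)), 0.1)
  expect_error(render_map(pairs, c(1000, 1000), -5), "positive")
})
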