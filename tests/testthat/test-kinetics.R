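test_that("bell_rate is the exact exponential law with sign convention", {
  bp <- bell_params(3e-2, 0.9)
  expect_equal(bell_rate(0, bp), 3e-2)
  # frozen from high-precision evaluation of 0.03 * exp(7*0.9/4.1)
  expect_equal(bell_rate(7, bp), 0.1394606869, tolerance = 1e-8)
  expect_true(is.finite(bell_rate(500, bp)))  # log-space evaluation
  fold <- bell_params(100, 5, "folding")
  expect_true(all(diff(bell_rate(1:10, fold)) < 0))
  expect_error(bell_params(-1, 0.5), "k0")
  expect_error(bell_params(1, 0.5, sign = 2), "sign")
})

test_that("Evans-Ritchie density normalizes and peaks at the closed form", {
  bp <- bell_params(2.4e-2, 0.7)
  total <- integrate(function(f) evans_ritchie_pdf(f, bp, 1), 0, 200,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-3)
  # argmax equals the closed-form mode
  mode_num <- optimize(function(f) evans_ritchie_pdf(f, bp, 1),
                       c(0, 60), maximum = TRUE)$maximum
  expect_equal(mode_num, most_probable_force(bp, 1), tolerance = 1e-6)
  # immediate-rupture limit
  expect_identical(most_probable_force(bell_params(1e3, 0.7), 1), 0)
})

test_that("most probable force reproduces the printed construct modes", {
  # LE-CSP-GS ramp-fit parameters -> ~11.5 pN
  expect_equal(most_probable_force(bell_params(2.4e-2, 0.7), 1), 11.5,
               tolerance = 0.01)
  # KL-CSP-GS parameters -> analytic 13.2 pN (paper's histogram fit: 13.6)
  expect_equal(most_probable_force(bell_params(1.2e-2, 0.9), 1), 13.24,
               tolerance = 0.01)
})

test_that("rupture-force sampling matches the analytic distribution", {
  bp <- bell_params(2.4e-2, 0.7)
  s1 <- sample_rupture_forces(1000, bp, 1, seed = 11)
  s2 <- sample_rupture_forces(1000, bp, 1, seed = 11)
  expect_identical(s1, s2)
  ks <- ks_distance(sample_rupture_forces(2e4, bp, 1, seed = 12),
                    function(f) er_cdf_oracle(f, 2.4e-2, 0.7, 1))
  expect_lt(ks, 0.012)
  # sample mean within 3 standard errors of the quadrature mean
  m <- er_mean_oracle(2.4e-2, 0.7, 1)
  s <- er_sd_oracle(2.4e-2, 0.7, 1)
  expect_lt(abs(mean(s1) - m), 3 * s / sqrt(length(s1)))
})

test_that("fit_bell recovers parameters from rate estimates", {
  beta <- 4.1
  truth <- bell_params(3e-2, 0.9)
  rates <- data.frame(force = 4:8, rate = bell_rate(4:8, truth))
  fit <- fit_bell(rates, beta)
  expect_equal(fit$k0, truth$k0, tolerance = 1e-8)
  expect_equal(fit$x, truth$x, tolerance = 1e-8)
  expect_identical(fit$sign, 1L)

  # folding branch: decreasing rates give sign -1 and positive x
  ftruth <- bell_params(100, 5, -1L)
  ffit <- fit_bell(data.frame(force = 4:8, rate = bell_rate(4:8, ftruth)),
                   beta)
  expect_identical(ffit$sign, -1L)
  expect_equal(ffit$x, 5, tolerance = 1e-8)

  # Monte-Carlo: 10% lognormal noise, 5 forces x 100 replicates
  set.seed(31)
  k0s <- replicate(100, {
    r <- bell_rate(4:8, truth) * exp(rnorm(5, 0, 0.1))
    fit_bell(data.frame(force = 4:8, rate = r,
                        stderr = 0.1 * r), beta)$k0
  })
  expect_lt(abs(median(k0s) / truth$k0 - 1), 0.15)

  expect_error(fit_bell(rates[1:2, ], beta), ">= 3")
})

test_that("ramp-distribution MLE recovers parameters from perfect samples", {
  bp <- bell_params(2.4e-2, 0.7)
  # deterministic quantile sample: recovery within 1%
  p <- (seq_len(500) - 0.5) / 500
  fperf <- mtfold:::rupture_quantile(p, bp, 1)
  fit <- fit_ramp_distribution(fperf, 1, n_boot = 0)
  expect_equal(fit$k0, bp$k0, tolerance = 0.01)
  expect_equal(fit$x, bp$x, tolerance = 0.01)

  # minimum-size boundary: runs and reports finite bootstrap errors
  f20 <- mtfold:::rupture_quantile((seq_len(20) - 0.5) / 20, bp, 1)
  fit20 <- fit_ramp_distribution(f20, 1, n_boot = 50, seed = 5)
  expect_true(is.finite(fit20$k0_err) && is.finite(fit20$x_err))
  expect_error(fit_ramp_distribution(f20[1:10], 1), ">= 20")

  # histogram least-squares mode agrees loosely with the MLE
  s <- sample_rupture_forces(2000, bp, 1, seed = 21)
  fh <- fit_ramp_distribution(s, 1, method = "histogram", n_boot = 0)
  expect_equal(fh$x, bp$x, tolerance = 0.15)
})

test_that("ramp-fit estimator bias shrinks with sample size", {
  bp <- bell_params(2.4e-2, 0.7)
  err <- vapply(c(50, 500, 5000), function(n) {
    s <- sample_rupture_forces(n, bp, 1, seed = 100 + n)
    abs(log(fit_ramp_distribution(s, 1, n_boot = 0)$k0 / bp$k0))
  }, numeric(1))
  expect_lt(err[3], 0.1)
  expect_lt(err[3], err[1])
})

test_that("critical force matches the rate-law crossing", {
  beta <- 4.1
  # constructed crossing at exactly 7 pN
  un <- bell_params(1e-2, 0.9)
  kf0 <- bell_rate(7, un, beta) * exp(7 * 5 / beta)
  fo <- bell_params(kf0, 5, -1L)
  fc <- critical_force(un, fo, beta)
  expect_equal(fc, 7, tolerance = 1e-9)
  expect_equal(bell_rate(fc, un, beta), bell_rate(fc, fo, beta),
               tolerance = 1e-9)
  # brute-force grid scan oracle
  grid <- seq(0, 20, by = 1e-4)
  cross <- grid[which.min(abs(bell_rate(grid, un, beta) -
                                bell_rate(grid, fo, beta)))]
  expect_equal(fc, cross, tolerance = 1e-4)
  # degenerate: equal zero-force rates
  expect_warning(fc0 <- critical_force(bell_params(1, 1),
                                       bell_params(1, 1, -1L), beta))
  expect_identical(fc0, 0)
})

test_that("barrier heights follow the Arrhenius inversion", {
  expect_equal(barrier_height(1e6, 1e6), 0)
  expect_equal(barrier_height(3e-2, 1e6), log(1e6 / 3e-2))
  expect_equal(barrier_height(3e-2, 1e6), 17.32, tolerance = 0.01)
  expect_equal(barrier_height(2.2e-3, 1e6), 19.93, tolerance = 0.01)
  expect_error(barrier_height(2, 1), "attempt")
})
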