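test_that("moving-average smoothing behaves as expected", {
  x <- rnorm(5000, sd = 6)
  expect_identical(smooth_height(x, 1), x)
  expect_equal(smooth_height(rep(3, 100), 20), rep(3, 100))
  # variance of the mean: sd shrinks by sqrt(window) away from the edges
  s <- smooth_height(x, 20)
  core <- s[50:(length(s) - 50)]
  expect_equal(sd(core), 6 / sqrt(20), tolerance = 0.1 * 6 / sqrt(20))
  expect_error(smooth_height(x[1:10], 20), "exceeds")
})

test_that("occupancy fit resolves a constructed two-Gaussian mixture", {
  set.seed(51)
  h <- c(rnorm(10000, 0, 1.3), rnorm(10000, 11, 1.3))
  occ <- fit_occupancy(h)
  expect_equal(occ$weight_U, 0.5, tolerance = 0.02)
  expect_equal(occ$mean_N, 0, tolerance = 0.1)
  expect_equal(occ$mean_U, 11, tolerance = 0.1)
  expect_lt(occ$mean_N, occ$mean_U)

  # single-state input collapses and must error
  expect_error(fit_occupancy(rnorm(5000, 0, 1.3)), "degenerate")
  expect_error(fit_occupancy(rnorm(100)), ">= 1000")
})

test_that("occupancy, HMM fractions and ground truth agree on P_u", {
  m <- csp_construct("LE-CSP-GS")
  tr <- simulate_constant_force(m, 6, 500, noise_sigma = 4, seed = 52)
  truth <- mean(tr$true_state == "U")
  occ <- fit_occupancy(smooth_height(tr, 20))
  seg <- hmm_segment(tr)
  p_hmm <- mean(seg$states == "U")
  expect_equal(occ$weight_U, truth, tolerance = 0.03)
  expect_equal(p_hmm, truth, tolerance = 0.03)
})

test_that("HMM segmentation recovers the state path", {
  # noiseless trace decodes exactly
  m <- make_simple_model()
  tr0 <- simulate_constant_force(m, 7, 40, noise_sigma = 1e-3, seed = 53)
  seg0 <- hmm_segment(tr0)
  expect_identical(seg0$states, tr0$true_state)

  # SNR 2.5 telegraph (15 nm step, 6 nm noise), rates 0.1/0.1 at 200 Hz:
  # per-sample accuracy of at least 99% against the simulator labels
  set.seed(54)
  t_tot <- 500; sr <- 200
  trans <- cumsum(rexp(300, 0.1))
  trans <- trans[trans < t_tot]
  tt <- (seq_len(t_tot * sr) - 1) / sr
  is_u <- (findInterval(tt, trans) %% 2) == 1
  y <- 15 * is_u + rnorm(length(tt), 0, 6)
  seg <- hmm_segment(y)
  acc <- mean((seg$states == "U") == is_u)
  expect_gte(acc, 0.99)
  # states ordered by emission mean: N is always the lower state
  expect_lt(seg$mean_N, seg$mean_U)
})

test_that("dwell extraction is a run-length identity", {
  states <- c("N", "N", "N", "U", "U", "N")
  dw <- extract_dwells(states, 200, 7)
  expect_equal(dw$state, c("N", "U", "N"))
  expect_equal(dw$duration_s, c(3, 2, 1) / 200)
  expect_equal(dw$censored, c(TRUE, FALSE, TRUE))
  expect_equal(dw$censored_start, c(TRUE, FALSE, FALSE))
  expect_equal(dw$censored_end, c(FALSE, FALSE, TRUE))
  # conservation: dwells partition the trace
  expect_equal(sum(dw$duration_s), length(states) / 200)
})

test_that("decoded transition counts match the simulator", {
  # SNR >= 3: step ~12.7 nm at 6 pN, noise 4 nm
  m <- csp_construct("LE-CSP-GS")
  n_true <- 0; n_dec <- 0
  for (s in 55:59) {   # ~180 events pooled, so 5% is beyond counting noise
    tr <- simulate_constant_force(m, 6, 500, noise_sigma = 4, seed = s)
    seg <- hmm_segment(tr)
    n_true <- n_true + nrow(attr(tr, "events"))
    n_dec <- n_dec + sum(!extract_dwells(seg$states, 200, 6)$censored_end)
  }
  expect_lt(abs(n_dec - n_true) / n_true, 0.05)
})

test_that("survival fit implements the exponential MLE", {
  dw <- data.frame(state = "N", duration_s = c(1, 1, 1, 1), force_pN = 7,
                   censored = FALSE, censored_start = FALSE,
                   censored_end = FALSE)
  fit <- survival_fit(dw, "N", min_events = 4)
  expect_equal(fit$rate, 1)
  expect_equal(fit$stderr, 0.5)

  # recovery from simulated exponential dwells
  set.seed(56)
  d2 <- data.frame(state = "N", duration_s = rexp(1000, 0.14), force_pN = 7,
                   censored = FALSE, censored_start = FALSE,
                   censored_end = FALSE)
  f2 <- survival_fit(d2, "N")
  expect_lt(abs(f2$rate - 0.14), 3 * 0.14 / sqrt(1000))
  # MLE and cumulative-curve fit agree
  f3 <- survival_fit(d2[1:200, ], "N")
  expect_equal(attr(f3, "cumulative_fit"), f3$rate, tolerance = 0.1)

  # all dwells censored -> error
  dc <- transform(d2[1:20, ], censored = TRUE, censored_start = TRUE,
                  censored_end = TRUE)
  expect_error(survival_fit(dc, "N"), "censored")
})

test_that("dead-time truncation with shifted origin stays unbiased", {
  set.seed(57)
  t <- rexp(4000, 2)
  dw <- data.frame(state = "N", duration_s = t, force_pN = 20,
                   censored = FALSE, censored_start = FALSE,
                   censored_end = FALSE)
  fit <- survival_fit(dw, "N", min_dwell = 0.2)
  expect_lt(abs(fit$rate - 2), 3 * 2 / sqrt(fit$n_events))
})

test_that("step detection finds single steps and rejects flat traces", {
  set.seed(58)
  y <- c(rnorm(2000, 0, 6), rnorm(2000, 15, 6))
  ev <- detect_steps(y, window = 20, threshold_sigma = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$step_nm, 15, tolerance = 1.5)
  expect_equal(ev$time_s, 2000 / 200, tolerance = 0.05)

  # null simulation: no false positives at 5 sigma over 100 seeds
  fp <- sum(vapply(1:100, function(s) {
    set.seed(1000 + s)
    nrow(detect_steps(rnorm(2000, 0, 6), window = 20, threshold_sigma = 5))
  }, numeric(1)))
  expect_equal(fp, 0)

  # a step too close to the boundary is flagged unreliable
  y2 <- c(rnorm(10, 0, 0.5), rnorm(400, 15, 0.5))
  ev2 <- detect_steps(y2, window = 20, threshold_sigma = 5)
  expect_true(nrow(ev2) == 0 || !ev2$reliable[1])
})
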