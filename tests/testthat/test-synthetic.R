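test_that("simulation is deterministic given the seed", {
  m <- make_simple_model()
  t1 <- simulate_constant_force(m, 7, 20, seed = 1)
  t2 <- simulate_constant_force(m, 7, 20, seed = 1)
  expect_identical(t1, t2)
  t3 <- simulate_constant_force(m, 7, 20, seed = 2)
  expect_false(identical(t1$height_nm, t3$height_nm))

  r1 <- simulate_ramp(m, force_protocol_ramp(2, 30, 1), seed = 3)
  r2 <- simulate_ramp(m, force_protocol_ramp(2, 30, 1), seed = 3)
  expect_identical(r1, r2)
})

test_that("trajectory container honours its invariants", {
  m <- make_simple_model()
  tr <- simulate_constant_force(m, 7, 10, seed = 4)
  expect_s3_class(tr, "trajectory")
  expect_equal(nrow(tr), 10 * 200)
  dt <- diff(tr$time_s)
  expect_equal(max(abs(dt - 1 / 200)), 0, tolerance = 1e-12)
  expect_true(all(tr$true_state %in% c("N", "U")))
})

test_that("symmetric rates give half occupancy of the unfolded state", {
  m <- make_flat_model(0.1, 0.1)
  occ <- vapply(1:20, function(s) {
    tr <- simulate_constant_force(m, 7, 500, noise_sigma = 0, seed = s)
    mean(tr$true_state == "U")
  }, numeric(1))
  expect_equal(mean(occ), 0.5, tolerance = 0.05)
})

test_that("dwell times are exponential with the requested rate", {
  m <- make_flat_model(0.5, 0.5)
  tr <- simulate_constant_force(m, 7, 4000, noise_sigma = 0, seed = 6)
  dw <- extract_dwells(tr$true_state, 200, 7)
  nd <- dw$duration_s[dw$state == "N" & !dw$censored]
  expect_gt(length(nd), 800)
  # mean dwell within 3 standard errors of 1/k_u (exponential oracle);
  # sampling at 200 Hz discretizes durations, adding ~ +1/2 sample bias
  expect_lt(abs(mean(nd) - 1 / 0.5 - 0.5 / 200),
            3 * (1 / 0.5) / sqrt(length(nd)))
})

test_that("noiseless heights are a two-level telegraph signal", {
  m <- make_simple_model()
  tr <- simulate_constant_force(m, 7, 60, noise_sigma = 0, seed = 7)
  lv <- sort(unique(round(tr$height_nm, 9)))
  expect_length(lv, 2)
  expect_equal(diff(lv), step_size(7, m$elasticity), tolerance = 1e-9)
  # labels consistent with heights before noise
  expect_equal(as.numeric(tapply(tr$height_nm, tr$true_state, mean)), lv)
})

test_that("ramp first-unfolding forces follow the analytic distribution", {
  m <- make_simple_model(ku0 = 2.4e-2, xu = 0.7, kf0 = 1e-6, xf = 5)
  prot <- force_protocol_ramp(2, 35, 1, relax = FALSE)
  first <- vapply(1:500, function(s) {
    tr <- simulate_ramp(m, prot, noise_sigma = 0, seed = 1000 + s)
    ev <- attr(tr, "events")
    ev$force_pN[ev$direction == "unfold"][1]
  }, numeric(1))
  expect_true(all(is.finite(first)))
  # exact inverse-hazard sampling: only sampling noise remains (n = 500,
  # the 1%-level one-sample KS bound is 0.073)
  ks <- ks_distance(first, function(f)
    er_cdf_oracle(f, 2.4e-2, 0.7, 1, f0 = 2) /
      er_cdf_oracle(35, 2.4e-2, 0.7, 1, f0 = 2))
  expect_lt(ks, 0.08)
})

test_that("loading/unloading ramps show folding hysteresis", {
  # qualitative ordering: refolds on the unloading leg sit below the
  # unfolding events of the loading leg (equilibrium hopping near the
  # critical force blurs individual pairs, so the check is distributional)
  m <- csp_construct("LE-CSP-GS")
  ordered <- logical(0)
  un_all <- numeric(0); re_all <- numeric(0)
  for (s in 1:40) {
    tr <- simulate_ramp(m, force_protocol_ramp(2, 42, 1), noise_sigma = 0,
                        seed = 2000 + s)
    ev <- attr(tr, "events")
    loading <- ev$time_s < 40
    un <- ev$force_pN[ev$direction == "unfold" & loading]
    re <- ev$force_pN[ev$direction == "refold" & !loading]
    un_all <- c(un_all, un); re_all <- c(re_all, re)
    if (length(un) > 0 && length(re) > 0) {
      ordered <- c(ordered, re[1] < max(un))
    }
  }
  expect_gt(length(ordered), 20)
  expect_gte(mean(ordered), 0.85)
  expect_lt(median(re_all), median(un_all))
})

test_that("a noiseless ramp trace steps exactly at the recorded rupture", {
  m <- make_simple_model(kf0 = 1e-6)
  tr <- simulate_ramp(m, force_protocol_ramp(2, 35, 1, relax = FALSE),
                      noise_sigma = 0, seed = 9)
  ev <- attr(tr, "events")
  expect_equal(nrow(ev), 1)
  jumps <- which(abs(diff(tr$height_nm)) > 1)
  expect_length(jumps, 1)
  expect_equal(tr$force_pN[jumps + 1], ev$force_pN[1], tolerance = 0.01)
})

test_that("force jumps: survival after the jump is exponential", {
  m <- make_simple_model(ku0 = 2.4e-2, xu = 0.7, kf0 = 200, xf = 5)
  k20 <- unfolding_rate(m, 20)
  first <- vapply(1:800, function(s) {
    tr <- simulate_force_jump(m, hold_forces = c(1, 20),
                              durations = c(0.5, 8), noise_sigma = 0,
                              seed = 3000 + s)
    ev <- attr(tr, "events")
    un <- ev$time_s[ev$force_pN == 20]
    if (length(un) > 0) un[1] - 0.5 else NA_real_
  }, numeric(1))
  obs <- first[!is.na(first)]
  # censoring-aware MLE against the known hold length
  k_hat <- length(obs) / (sum(obs) + sum(is.na(first)) * 8)
  expect_equal(k_hat, k20, tolerance = 0.1)
})

test_that("a one-segment jump schedule reduces to the constant-force path", {
  m <- make_simple_model()
  a <- simulate_force_jump(m, hold_forces = 7, durations = 15, seed = 17)
  b <- simulate_constant_force(m, 7, 15, seed = 17)
  expect_equal(a$height_nm, b$height_nm)
  expect_equal(a$true_state, b$true_state)
})

test_that("jump step sizes track the polymer model", {
  m <- csp_construct("LE-CSP-GS")
  for (f in c(12, 25)) {
    tr <- simulate_force_jump(m, hold_forces = c(1, f), durations = c(1, 30),
                              noise_sigma = 1, seed = 40 + f)
    hold <- tr[tr$time_s >= 1, , drop = FALSE]
    ev <- detect_steps(hold, window = 20, threshold_sigma = 5)
    ev <- ev[ev$step_nm > 0, , drop = FALSE]
    if (nrow(ev) > 0) {
      expect_equal(ev$step_nm[1], step_size(f, m$elasticity), tolerance = 1)
    }
  }
})

test_that("optional noise and calibration modes behave as declared", {
  m <- make_simple_model()
  # Ornstein-Uhlenbeck mode: same marginal s.d., correlated samples
  tr <- simulate_constant_force(m, 7, 60, noise_sigma = 6, seed = 90,
                                noise_corner = 10)
  noise <- tr$height_nm - ifelse(tr$true_state == "U",
                                 step_size(7, m$elasticity), 0)
  expect_equal(sd(noise), 6, tolerance = 0.5)
  rho <- cor(noise[-1], noise[-length(noise)])
  expect_equal(rho, exp(-2 * pi * 10 / 200), tolerance = 0.05)
  expect_identical(tr, simulate_constant_force(m, 7, 60, noise_sigma = 6,
                                               seed = 90,
                                               noise_corner = 10))

  # per-trace force-scale error shifts the true step size, not the record
  tr2 <- simulate_constant_force(m, 7, 60, noise_sigma = 0, seed = 91,
                                 force_scale_sd = 0.05)
  expect_true(all(tr2$force_pN == 7))
  lv <- sort(unique(round(tr2$height_nm, 9)))
  rel <- diff(lv) / step_size(7, m$elasticity) - 1
  expect_true(abs(rel) > 0 && abs(rel) < 0.3)
})

test_that("protocol validation rejects out-of-range forces", {
  expect_error(force_protocol_constant(0.01, 10), "0.1")
  expect_error(force_protocol_ramp(5, 4), "exceed")
  expect_error(force_protocol_jump(c(1, 70), c(1, 1)), "60")
  m <- make_flat_model(150, 150)
  expect_warning(simulate_constant_force(m, 7, 1, seed = 1), "undersampled")
})
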