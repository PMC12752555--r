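test_that("transition-state positions add the fitted distances to N", {
  m <- csp_construct("KL-CSP-GS")
  pos <- transition_state_positions(m)
  expect_equal(unname(pos["N"]), 1.3)
  expect_equal(unname(pos["TS1"]), 1.8)   # 1.3 + 0.5
  expect_equal(unname(pos["TS2"]), 2.7)   # 1.3 + 1.4
  expect_equal(unname(transition_state_positions(
    csp_construct("LE-CSP-GS"))["TS2"]), 2.2)
  expect_equal(unname(transition_state_positions(
    csp_construct("KL-CSP-LE"))["TS2"]), 3.0)
})

test_that("landscape energies compose dG0 and the barrier heights", {
  m <- csp_construct("LE-CSP-GS")
  en <- landscape_energies(m, delta_g0 = 8.9)
  expect_equal(unname(en["U"]), 0)
  expect_equal(unname(en["N"]), -8.9)
  # TS2: -8.9 + ln(1e6/0.03) = 8.42 k_BT above U
  expect_equal(unname(en["TS2"]), -8.9 + log(1e6 / 3e-2), tolerance = 1e-9)
  expect_equal(unname(en["TS2"]), 8.42, tolerance = 0.01)

  # dG0 = 0: N degenerate with U, TS energies are the bare barriers
  en0 <- landscape_energies(m, delta_g0 = 0)
  expect_equal(unname(en0["N"]), 0)
  expect_equal(unname(en0["TS2"]), barrier_height(m$low_force$k0))

  # raising k0 by a factor e lowers the barrier by exactly 1 k_BT
  m2 <- m
  m2$low_force <- bell_params(m$low_force$k0 * exp(1), m$low_force$x)
  expect_equal(unname(landscape_energies(m2, 8.9)["TS2"]),
               unname(en["TS2"]) - 1, tolerance = 1e-9)
})

test_that("unfolding-probability fit recovers dG0 and pins P_u(f_c) = 1/2", {
  ep <- elasticity_params()
  fs <- seq(3, 8, by = 0.5)
  gs <- stretch_free_energy(fs, ep)
  pu <- 1 / (1 + exp(9 - gs))
  fit <- fit_unfolding_probability(fs, pu, ep)
  expect_equal(fit$delta_g0, 9, tolerance = 1e-4)
  pu_at_fc <- 1 / (1 + exp(fit$delta_g0 -
                             stretch_free_energy(fit$critical_force, ep)))
  expect_equal(pu_at_fc, 0.5, tolerance = 1e-6)

  expect_error(fit_unfolding_probability(fs, rep(0.001, length(fs)), ep),
               "unidentifiable")
  expect_error(fit_unfolding_probability(1:3, c(0.2, 0.5, 0.8), ep), ">= 4")
})

test_that("the two dG0 routes agree on data from the same rate laws", {
  m <- csp_construct("LE-CSP-GS")
  # route 1: coexistence work at the rate crossing
  dg_rates <- delta_g0_from_rates(m$low_force, m$folding, m$elasticity)
  expect_equal(as.numeric(dg_rates), m$delta_g0_ref, tolerance = 1e-6)
  # route 2: P_u(f) computed from the rate laws, then the logistic fit
  fs <- seq(4, 8, by = 0.25)
  pu <- unfolding_rate(m, fs) / (unfolding_rate(m, fs) + folding_rate(m, fs))
  dg_pu <- fit_unfolding_probability(fs, pu, m$elasticity)$delta_g0
  expect_lt(abs(dg_pu - as.numeric(dg_rates)), 0.3)

  # constructed crossing: dG0 equals the stretching work exactly
  un <- bell_params(1e-2, 0.9)
  kf0 <- bell_rate(7, un) * exp(7 * 5 / 4.1)
  dg <- delta_g0_from_rates(un, bell_params(kf0, 5, -1L), m$elasticity)
  expect_equal(as.numeric(dg), stretch_free_energy(7, m$elasticity),
               tolerance = 1e-6)

  # no crossing -> error
  expect_error(
    suppressWarnings(delta_g0_from_rates(bell_params(1, 0.9),
                                         bell_params(0.5, 5, -1L),
                                         m$elasticity)),
    "crossing")
})

test_that("construct ordering of dG0 matches the published ranking", {
  dg <- vapply(c("LE-CSP-GS", "KL-CSP-GS", "KL-CSP-LE"), function(id) {
    m <- csp_construct(id)
    as.numeric(delta_g0_from_rates(m$low_force, m$folding, m$elasticity))
  }, numeric(1))
  expect_true(dg[1] < dg[2] && dg[2] < dg[3])
})

test_that("landscape reconstruction satisfies the ordering invariants", {
  for (id in c("LE-CSP-GS", "KL-CSP-GS", "KL-CSP-LE")) {
    ls <- reconstruct_landscape(csp_construct(id))
    p <- ls$positions
    expect_true(p[["N"]] < p[["TS1"]] && p[["TS1"]] < p[["TS2"]])
    expect_gt(ls$energies[["TS1"]], ls$energies[["N"]])
    expect_gt(ls$energies[["TS2"]], ls$energies[["N"]])
    expect_gt(ls$delta_g0, 0)
  }
})

test_that("N-C distance is read from PDB alpha-carbons", {
  # constructed fixture: terminal CA atoms 13 Angstrom apart -> 1.3 nm
  p1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(synthetic_pdb(cbind(c(0, 5, 13), c(0, 4, 0), c(0, 2, 0))), p1)
  expect_equal(nc_distance_from_structure(p1), 1.3, tolerance = 1e-9)

  # multi-model entry: only the first model is used
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(synthetic_pdb(cbind(c(0, 13), 0, 0), model_no = 1),
               synthetic_pdb(cbind(c(0, 99), 0, 0), model_no = 2)), p2)
  expect_equal(nc_distance_from_structure(p2), 1.3, tolerance = 1e-9)

  # single-residue chain errors
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(synthetic_pdb(cbind(0, 0, 0)), p3)
  expect_error(nc_distance_from_structure(p3), "single residue|fewer")
})
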