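test_that("the SNc-to-DRN stimulation has the printed fixed point and limits", {
  expect_equal(stimulation(1, 0.000968), 1.0) # 1.5 - 0.5 at equilibrium
  expect_equal(stimulation(0, 0.5), 0)
  expect_equal(stimulation(1, 1e6), 0.5, tolerance = 1e-9)
  expect_equal(stimulation(1, 0), 1.5)
  expect_error(stimulation(1.2, 0.001), "\\[0, 1\\]")
  expect_error(stimulation(1, -0.1), "non-negative")
})

test_that("the drug binding equations conserve total SERT identically", {
  p <- calibrated_params()
  # derivative-level conservation: dF + dB = 0 for arbitrary states
  for (st in list(c(E = 0, F = 1, B = 0), c(E = 2, F = 0.4, B = 0.6),
                  c(E = 0.01, F = 0.9, B = 0.1))) {
    d <- escit_rhs(st, t = 1, params = p)
    expect_identical(d[["dF"]] + d[["dB"]], 0)
  }
  # no input, no drug: everything stays put
  d0 <- escit_rhs(c(E = 0, F = 1, B = 0), t = 0, params = monoamine_params())
  expect_equal(unname(d0), c(0, 0, 0))
  # fixed point of the binding pair: B/F = k1 E / k2
  E <- 0.8
  Bstar <- p$escit_k1 * E / (p$escit_k1 * E + p$escit_k2)
  d <- escit_rhs(c(E = E, F = 1 - Bstar, B = Bstar), t = 1e9, params = p)
  expect_equal(d[["dB"]], 0, tolerance = 1e-12)
  # trajectory-level conservation (F reconstructed from the bound state)
  occ <- serovolt:::simulate_occupancy(p, p$escit_I0, duration_h = 12)
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
})

test_that("the calibrated model reproduces its anchors at full SNc survival", {
  p <- calibrated_params()
  eq <- simulate_steady_state(1, p)
  expect_equal(eq$serotonin_nM, 35, tolerance = 0.01 * 35)
  expect_equal(eq$drn_uM, 0.000968, tolerance = 0.01 * 0.000968)
  expect_equal(eq$drive, 1, tolerance = 1e-6)
  # full SNc loss removes all hippocampal release drive
  eq0 <- simulate_steady_state(0, p)
  expect_equal(eq0$drive, 0, tolerance = 1e-10)
  expect_lt(eq0$serotonin_nM, 1e-6)
})

test_that("equilibria do not depend on the starting state", {
  p <- calibrated_params()
  far <- c(500, 500, 500, 500, 100, 50, 0, 0)
  eq1 <- simulate_steady_state(0.5, p)
  eq2 <- simulate_steady_state(0.5, p, init = far)
  expect_equal(eq1$state, eq2$state, tolerance = 1e-6)
})

test_that("degeneration sweeps bracket the printed serotonin decline", {
  p <- calibrated_params()
  sw <- degeneration_sweep(seq(0.2, 1, by = 0.1), p)
  expect_gte(sw$serotonin_rel[sw$f == 0.4], 34)
  expect_lte(sw$serotonin_rel[sw$f == 0.3], 43)
  # serotonin declines monotonically with cell death
  expect_true(all(diff(sw$serotonin_nM) > 0))
  # near-linear decline over f in [0.2, 1]
  r2 <- summary(lm(serotonin_rel ~ f, data = sw))$r.squared
  expect_gte(r2, 0.9)
  # dopamine homeostasis: barely drops at 80% cell loss
  expect_gte(sw$dopamine_rel[sw$f == 0.2] / 100, 0.7)
  expect_error(degeneration_sweep(numeric(0)), "empty")
})

test_that("simulated escitalopram raises serotonin with 50% peak occupancy", {
  p <- calibrated_params()
  ctrl <- simulate_escit_experiment(f = 1, params = p)
  mptp <- simulate_escit_experiment(f = 0.35, params = p)
  expect_equal(attr(ctrl, "peak_occupancy"), 0.5, tolerance = 0.01)
  # pre-dose segments sit flat at the f-dependent equilibria
  pre <- ctrl$time_min < 60
  expect_lt(diff(range(ctrl$serotonin_nM[pre])), 1e-4)
  expect_equal(attr(mptp, "baseline_nM"), mptp$serotonin_nM[1],
               tolerance = 1e-6)
  rise_ctrl <- max(ctrl$serotonin_nM) - attr(ctrl, "baseline_nM")
  rise_mptp <- max(mptp$serotonin_nM) - attr(mptp, "baseline_nM")
  expect_gt(rise_ctrl, 0)
  expect_gt(rise_mptp, 0)
  expect_gt(rise_ctrl, rise_mptp) # blunted SSRI response after MPTP
  expect_error(simulate_escit_experiment(dose_time_min = -5), "non-negative")
})

test_that("levodopa dopamine pulses are non-monotone in SNc survival", {
  p <- calibrated_params()
  amps <- vapply(c(0.01, 0.1, 0.2, 1), function(f) {
    attr(simulate_ldopa(f, params = p), "amplitude")
  }, numeric(1))
  names(amps) <- c("f001", "f01", "f02", "f1")
  expect_gt(amps[["f02"]], amps[["f1"]])   # fewer DATs: bigger pulse
  expect_lt(amps[["f001"]], amps[["f01"]]) # sparse terminals: pulse collapses
  # interior maximum
  expect_gt(max(amps[c("f01", "f02")]), max(amps[c("f001", "f1")]))
  flat <- simulate_ldopa(0.5, dose = 0, params = p)
  expect_lt(diff(range(flat$dopamine_nM)), 1e-5)
  expect_error(simulate_ldopa(0.5, dose = -1, params = p), "non-negative")
})

test_that("all states stay non-negative across a scenario grid", {
  p <- calibrated_params()
  for (f in c(0.05, 0.35, 1)) {
    esc <- simulate_escit_experiment(f = f, duration_min = 180, params = p)
    expect_true(all(esc$serotonin_nM >= 0))
    expect_true(all(esc$occupancy >= 0 & esc$occupancy <= 1))
    ld <- simulate_ldopa(f, params = p, duration_h = 4)
    expect_true(all(ld$dopamine_nM >= 0))
    expect_true(all(ld$serotonin_nM >= 0))
  }
})
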