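test_that("charge integration recovers an analytic Gaussian peak", {
  ws <- waveform_spec()
  axis <- build_waveform(ws)
  w <- 0.03
  amp <- 2 # nA
  cur <- amp * exp(-(axis - 0.6)^2 / (2 * w^2))
  cur[-serovolt:::anodic_indices(axis)] <- 0
  q <- fscav_charge(cur, axis, sample_rate = ws$sample_rate)
  # dphi/dt = scan rate, so the time integral is amp*w*sqrt(2pi)/1000 nA s
  expected_pC <- 1000 * amp * w * sqrt(2 * pi) / ws$scan_rate
  expect_equal(q, expected_pC, tolerance = 0.01)

  expect_equal(fscav_charge(rep(0, 220), axis), 0)
  off_peak <- 0.5 * exp(-(axis - 0.1)^2 / (2 * w^2))
  expect_lt(abs(fscav_charge(off_peak, axis)),
            0.02 * expected_pC)
  expect_error(fscav_charge(cur[1:50], axis[1:50]), "cover")
})

test_that("the four-point calibration recovers an exact line", {
  calib <- fscav_calibration()
  expect_equal(calib$standards$concentration, c(10, 25, 50, 100))
  charges <- c(4, 11, 23, 48)
  line <- fscav_calibration(concentration = 3 * charges + 1, charge = charges)
  expect_equal(line$slope, 3)
  expect_equal(line$intercept, 1)
  # round trip concentration -> charge -> concentration
  conc <- c(12, 33.3, 71)
  back <- calibrate_fscav(line, (conc - line$intercept) / line$slope)
  expect_equal(back, conc)
  expect_error(fscav_calibration(charge = rep(2, 4)), "degenerate")
})

test_that("synthetic ambient series carry the group baselines and slopes", {
  ctrl <- generate_fscav_series("control", noise_sd = 0, seed = 1)
  mptp <- generate_fscav_series("mptp", noise_sd = 0, seed = 1)
  expect_equal(ctrl$concentration[1], 32.65)
  expect_equal(mptp$concentration[1], 11.46)
  expect_true(all(diff(ctrl$time) == 1)) # one sample per minute
  sl <- fscav_epoch_slopes(ctrl)
  expect_equal(sl$slope[sl$label == "control"], 0, tolerance = 1e-10)
  expect_equal(sl$slope[sl$label == "escit"], 0.39, tolerance = 1e-10)
  expect_equal(fscav_epoch_slopes(mptp)$slope[3], 0.21, tolerance = 1e-10)
  expect_equal(ctrl$events$label, c("saline", "escit"))
  expect_equal(ctrl$events$time, c(30, 60))
  # charge is consistent with the calibration line
  expect_equal(calibrate_fscav(fscav_calibration(), ctrl$charge),
               ctrl$concentration)
  expect_error(generate_fscav_series(baseline = -1), "baseline")
})

test_that("series generation is reproducible and writable", {
  a <- generate_fscav_series("control", seed = 7)
  b <- generate_fscav_series("control", seed = 7)
  expect_identical(a$concentration, b$concentration)
  path <- tempfile(fileext = ".csv")
  write_fscav_series(a, path)
  back <- read_fscav_series(path)
  expect_equal(back$concentration, a$concentration, tolerance = 1e-12)
  expect_equal(back$events$label, c("saline", "escit"))
})

test_that("the escitalopram response summary reproduces the group differences", {
  means <- fscav_reference_means()
  out <- escit_effect_summary(setNames(means$before, means$group),
                              setNames(means$after, means$group))
  d <- out$differences
  expect_equal(d$difference[d$group == "control"], 32.69)
  expect_equal(d$difference[d$group == "mptp"], 15.23)
  same <- escit_effect_summary(c(a = 5, b = 7), c(a = 5, b = 7))
  expect_true(all(same$differences$difference == 0))
  expect_error(escit_effect_summary(c(a = 1), c(b = 2)), "labels")
})
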