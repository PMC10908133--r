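test_that("current-to-concentration conversion applies the 49.5 nM/nA factor", {
  expect_equal(current_to_concentration(1), 49.5)
  expect_equal(current_to_concentration(0), 0)
  expect_equal(current_to_concentration(2), 99.0)
  expect_equal(current_to_concentration(c(0.5, -1)), c(24.75, -49.5))
})

test_that("trace extraction inverts the noiseless plot construction", {
  ws <- waveform_spec()
  tpl <- analyte_template("serotonin", ox_center = 0.65)
  tt <- (0:49) / 10
  conc <- ifelse(tt >= 1, 30 * exp(-(tt - 1) / 2), 0)
  transient <- evoked_trace(tt, conc, stim_window = c(1, 2))
  p <- simulate_color_plot(tpl, transient, ws)
  tr <- extract_trace(p, 0.65)
  # the template row nearest 0.65 V is within the Gaussian peak (value ~1)
  expect_equal(tr$concentration, conc, tolerance = 1e-6)
  zero <- simulate_color_plot(tpl, evoked_trace(tt, rep(0, 50),
                                                stim_window = c(1, 2)), ws)
  expect_true(all(extract_trace(zero, 0.65)$concentration == 0))
  expect_error(extract_trace(p, 1.5), "outside")
})

test_that("peak amplitude subtracts the pre-stimulation baseline", {
  tt <- (0:99) / 10
  bump <- ifelse(tt >= 2, 12 * exp(-(tt - 2)) * (1 - exp(-4 * (tt - 2))), 0)
  tr <- evoked_trace(tt, bump + 5, stim_window = c(2, 2))
  expect_equal(peak_amplitude(tr), max(bump), tolerance = 1e-9)
  flat <- evoked_trace(tt, rep(0, 100), stim_window = c(2, 2))
  expect_equal(peak_amplitude(flat), 0)
  shifted <- evoked_trace(tt, bump + 105, stim_window = c(2, 2))
  expect_equal(peak_amplitude(shifted), peak_amplitude(tr), tolerance = 1e-9)
})

test_that("peak amplitude of a simulated release matches a dense forward run", {
  p <- mm_group_params()$saline
  tr <- simulate_mm(p, duration = 20, dt = 0.1)
  dense <- simulate_mm(p, duration = 20, dt = 0.001)
  expect_equal(peak_amplitude(tr), max(dense$concentration),
               tolerance = 1e-3)
})

test_that("Simpson integration is exact on polynomials and the half-sine", {
  tt <- (0:100) / 10
  const <- evoked_trace(tt, rep(3, 101))
  expect_equal(auc_simpson(const), 3 * 10)
  quad <- evoked_trace(tt, 2 * tt^2 - tt + 1)
  expect_equal(auc_simpson(quad), 2 * 1000 / 3 - 100 / 2 + 10,
               tolerance = 1e-12)
  # odd interval count exercises the trapezoid fallback
  quad_even <- evoked_trace(tt[1:100], (2 * tt^2 - tt + 1)[1:100])
  expect_equal(auc_simpson(quad_even),
               (2 * 9.9^3 / 3 - 9.9^2 / 2 + 9.9), tolerance = 1e-3)
  L <- 10
  half_sine <- evoked_trace(tt, 4 * sin(pi * tt / L))
  expect_equal(auc_simpson(half_sine), 2 * 4 * L / pi, tolerance = 1e-6)
  expect_error(auc_simpson(const, window = c(0, 0.1)), "3 samples")
})

test_that("half-life inverts exponential decay", {
  tt <- (0:200) / 10
  k <- 0.347
  tr <- evoked_trace(tt, 30 * exp(-k * tt))
  expect_equal(half_life(tr), log(2) / k, tolerance = 1e-6)
  expect_equal(half_life(tr), 2.0, tolerance = 1e-2)
  tr2 <- evoked_trace(tt, 30 * exp(-2 * k * tt))
  expect_equal(half_life(tr2), half_life(tr) / 2, tolerance = 1e-6)
  rising <- evoked_trace(tt, c(10, seq(1, 9.5, length.out = 200)))
  expect_error(half_life(rising), "decay")
})

test_that("traces round-trip through CSV", {
  tt <- (0:30) / 10
  tr <- evoked_trace(tt, sin(tt) + 2, stim_window = c(0.5, 2))
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$concentration, tr$concentration, tolerance = 1e-12)
  expect_equal(back$stim_window, c(0.5, 2))
})
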