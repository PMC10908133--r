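make_transient <- function(n = 40, hz = 10, t0 = 0.5, amp = 20) {
  tt <- (seq_len(n) - 1) / hz
  conc <- ifelse(tt >= t0, amp * exp(-(tt - t0)), 0)
  evoked_trace(tt, conc, stim_window = c(t0, 2))
}

test_that("simulated color plots follow the template-transient construction", {
  ws <- waveform_spec()
  tpl <- analyte_template("serotonin")
  tr <- make_transient()
  zero_tr <- evoked_trace(tr$time, rep(0, length(tr$time)),
                          stim_window = tr$stim_window)
  p0 <- simulate_color_plot(tpl, zero_tr, ws, n_rows = 32)
  expect_true(all(p0$current == 0))

  p <- simulate_color_plot(tpl, tr, ws, n_rows = 32)
  sig <- make_template(tpl, ws, n_samples = 32)
  row <- which.max(sig)
  expect_equal(p$current[row, ], tr$concentration / 49.5 * sig[row],
               tolerance = 1e-12)
  expect_equal(dim(p$current), c(32L, 40L))
  expect_equal(diff(p$time_axis)[1], 1 / ws$repetition_hz)
})

test_that("plot simulation is a pure function of its seed", {
  ws <- waveform_spec()
  tpl <- analyte_template("serotonin")
  tr <- make_transient()
  a <- simulate_color_plot(tpl, tr, ws, n_rows = 24, noise_sd = 0.1, seed = 9)
  b <- simulate_color_plot(tpl, tr, ws, n_rows = 24, noise_sd = 0.1, seed = 9)
  c <- simulate_color_plot(tpl, tr, ws, n_rows = 24, noise_sd = 0.1, seed = 10)
  expect_identical(a$current, b$current)
  expect_false(identical(a$current, c$current))
  expect_error(simulate_color_plot(tpl, tr, ws, noise_sd = -1), "noise_sd")
})

test_that("standardization yields mean 0 / SD 1 and is idempotent and affine-invariant", {
  ws <- waveform_spec()
  p <- simulate_color_plot(analyte_template("serotonin"), make_transient(),
                           ws, n_rows = 24, noise_sd = 0.05, seed = 2)
  s <- standardize_plot(p)
  expect_lt(abs(mean(s$current)), 1e-9)
  expect_lt(abs(sd(s$current) - 1), 1e-9)
  s2 <- standardize_plot(s)
  expect_equal(s2$current, s$current, tolerance = 1e-9)
  aff <- p
  aff$current <- 3.7 * p$current - 11
  expect_equal(standardize_plot(aff)$current, s$current, tolerance = 1e-9)
  const <- p
  const$current[] <- 2
  expect_error(standardize_plot(const), "constant")
})

test_that("color plots round-trip bit-exactly through the CSV dialect", {
  ws <- waveform_spec()
  p <- simulate_color_plot(analyte_template("dopamine"), make_transient(),
                           ws, n_rows = 24, noise_sd = 0.2, seed = 4,
                           meta = list(animal = "d_1", id = "d_1_1"))
  path <- tempfile(fileext = ".csv")
  write_color_plot(p, path)
  q <- read_color_plot(path)
  expect_identical(q$current, p$current)
  expect_equal(q$potential_axis, p$potential_axis)
  expect_equal(q$meta$animal, "d_1")
})
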