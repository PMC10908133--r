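test_that("serotonin waveform geometry follows the vertex path and scan rate", {
  ws <- waveform_spec()
  expect_equal(sweep_duration(ws), 2.2e-3) # 2.2 V path at 1000 V/s
  expect_equal(sweep_samples(ws), 220L)
  axis <- build_waveform(ws)
  expect_length(axis, 220L)
  expect_equal(axis[1], 0.2)
  expect_equal(axis[length(axis)], 0.2)
  # resampled sweeps keep the closed endpoints
  ax64 <- build_waveform(ws, n_samples = 64)
  expect_equal(ax64[c(1, 64)], c(0.2, 0.2))
})

test_that("non-closed waveforms are rejected", {
  expect_error(waveform_spec(vertices = c(0.2, 1.0, -0.1)), "closed")
  expect_error(waveform_spec(scan_rate = 0), "scan_rate")
})

test_that("analyte templates place their oxidation peaks correctly", {
  ws <- waveform_spec()
  axis <- build_waveform(ws)
  ser <- make_template(analyte_template("serotonin"), ws)
  dop <- make_template(analyte_template("dopamine"), ws)
  expect_equal(max(abs(ser)), 1)
  pk_ser <- axis[which.max(ser)]
  pk_dop <- axis[which.max(dop)]
  expect_gte(pk_ser, 0.4)
  expect_lte(pk_ser, 0.8)
  expect_false(isTRUE(all.equal(pk_ser, pk_dop)))
  # reduction trough is negative and on the cathodic segment
  expect_lt(min(ser), 0)
  expect_gt(which.min(ser), which.max(axis))
})

test_that("template edge cases are handled", {
  ws <- waveform_spec()
  expect_equal(make_template(analyte_template("serotonin"), ws,
                             amplitude_scale = 0),
               rep(0, 220))
  expect_error(analyte_template("serotonin", ox_center = 0.9), "0.4, 0.8")
  bad <- analyte_template("dopamine", ox_center = 2)
  expect_error(make_template(bad, ws), "outside")
  expect_error(analyte_template("serotonin", ox_width = 0), "width")
})
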