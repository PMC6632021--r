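test_that("generate_beat renders the requested morphology", {
  # degenerate: all amplitudes zero -> flat beat (R amplitude must stay
  # positive to pass validation, so scale it to numerical zero)
  m0 <- beat_morphology(p = c(0, 20, -180), q = c(0, 10, -25),
                        r = c(1e-12, 12, 0), s = c(0, 10, 25),
                        t = c(0, 25, 200))
  b0 <- generate_beat(m0, fs = 500, rr_ms = 1000)
  expect_lt(max(abs(b0$samples)), 1e-11)

  b <- generate_beat(beat_morphology(), fs = 500, rr_ms = 1000)
  expect_length(b$samples, 500L)
  expect_equal(which.max(b$samples) - 1L, b$r_center)
  # Q/S Gaussian tails overlap the R center and pull the peak down ~1%
  expect_equal(max(b$samples), 1.0, tolerance = 0.02)

  # injected ST plateau sits at the configured offset
  me <- beat_morphology(st_offset = 0.2)
  be <- generate_beat(me, fs = 500, rr_ms = 1000)$samples
  bn <- generate_beat(beat_morphology(), fs = 500, rr_ms = 1000)$samples
  plateau <- b$r_center + ((45:150) * 0.5)  # ms -> samples at 500 Hz
  idx <- unique(round(plateau))
  expect_equal(mean(be[idx] - bn[idx]), 0.2, tolerance = 0.02)

  expect_error(generate_beat(beat_morphology(), fs = -1, rr_ms = 100))
})

test_that("generate_record assembles annotated beats deterministically", {
  rec <- generate_record("NORMAL", n_beats = 10, fs = 500,
                         noise = noise_preset("none"), mean_bpm = 60)
  expect_length(rec$samples, 5000L)    # 10 s at 500 Hz
  expect_equal(nrow(rec$annotations), 10L)
  expect_true(all(rec$annotations$label == "NORMAL"))
  # R annotations sit on local maxima of the trace
  r1 <- rec$annotations$sample_index[3] + 1L
  expect_equal(rec$samples[r1], max(rec$samples[(r1 - 50):(r1 + 50)]))

  a <- generate_record("ST_ELEVATION", n_beats = 15, rr_jitter = 30,
                       noise = noise_preset("wearable", seed = 7))
  b <- generate_record("ST_ELEVATION", n_beats = 15, rr_jitter = 30,
                       noise = noise_preset("wearable", seed = 7))
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)

  expect_error(generate_record("BOGUS", 5), "invalid class")
})

test_that("ADC model quantizes with the device step and clips", {
  adc <- adc_config()
  expect_equal(round(adc_step(adc) * 1000, 2), 2.93)
  expect_equal(quantize_adc(0, adc), 0)
  expect_equal(quantize_adc(3.0 - 1e-9, adc), 1023)
  expect_equal(quantize_adc(c(-1, 99), adc), c(0, 1023))  # clipping contract
  set.seed(1)
  v <- runif(200, 0, 3)
  err <- abs(dequantize_adc(quantize_adc(v, adc), adc) - v)
  expect_lt(max(err), adc_step(adc))
})

test_that("battery arithmetic matches the device power budget", {
  expect_equal(battery_life(power_budget(1000, 9.3, 0.70)), 75.27,
               tolerance = 1e-3)
  expect_equal(battery_life(power_budget(0, 9.3)), 0)
  expect_equal(battery_life(power_budget(2000, 9.3)),
               2 * battery_life(power_budget(1000, 9.3)))
  expect_error(battery_life(power_budget(1000, 0)), "positive")

  expect_equal(required_capacity(24, 9.3, 0.70), 318.86, tolerance = 1e-2)
  expect_equal(required_capacity(0, 9.3), 0)
  # inverse identity
  h <- 17.5
  expect_equal(battery_life(power_budget(required_capacity(h, 9.3), 9.3)), h)
})
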