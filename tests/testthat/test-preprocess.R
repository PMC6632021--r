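test_that("moving average matches a direct windowed mean with reflected edges", {
  expect_equal(moving_average(rep(3.5, 50), 7), rep(3.5, 50))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)

  y <- moving_average(c(1, 2, 3, 4, 5), 3)
  expect_equal(y[2:4], c(2, 3, 4))
  expect_equal(y[1], mean(c(2, 1, 2)))  # reflect-padded edge
  expect_equal(y[5], mean(c(4, 5, 4)))

  # oracle on random input
  set.seed(4)
  x <- rnorm(30)
  xp <- c(x[3:2], x, x[29:28])
  direct <- vapply(1:30, function(i) mean(xp[i:(i + 4)]), numeric(1))
  expect_equal(moving_average(x, 5), direct, tolerance = 1e-12)

  expect_error(moving_average(x, 0), ">= 1")
})

test_that("baseline estimator flattens beats but follows slow trends", {
  z <- rep(0, 1000)
  expect_equal(estimate_baseline(z, 500), z)

  ramp <- seq(0, 1, length.out = 2000)
  b <- estimate_baseline(ramp, 500)
  interior <- 300:1700
  expect_lt(max(abs(b[interior] - ramp[interior])), 0.01)

  # a narrow 12 ms spike is rejected entirely
  spike <- rep(0, 1500); spike[700:706] <- 5
  expect_lt(max(abs(estimate_baseline(spike, 500))), 1e-9)

  expect_error(estimate_baseline(rep(0, 100), 500), "short")
})

test_that("baseline correction removes drift and is offset invariant", {
  rec <- clean_record("NORMAL", n_beats = 20)
  x <- rec$samples
  fs <- rec$fs
  expect_equal(correct_baseline(x + 0.7, fs), correct_baseline(x, fs),
               tolerance = 1e-10)

  # 0.3 Hz, 0.5 mV respiration drift: amplitude measured by projecting on
  # the quadrature pair before and after correction
  tt <- (seq_along(x) - 1) / fs
  drift <- 0.5 * sin(2 * pi * 0.3 * tt + 0.4)
  fit_amp <- function(y) {
    co <- coef(lm(y ~ sin(2 * pi * 0.3 * tt) + cos(2 * pi * 0.3 * tt)))
    sqrt(sum(co[2:3]^2))
  }
  corrected <- correct_baseline(x + drift, fs)
  expect_lt(fit_amp(corrected) / fit_amp(x + drift), 0.10)

  # corrected isoelectric (TP) segments sit within 0.05 mV of zero
  pre <- preprocess_record(rec)
  r <- rec$annotations$sample_index
  iso_idx <- unlist(lapply(r[-length(r)], function(ri)
    (ri + round(0.6 * fs)):(ri + round(0.75 * fs)))) + 1L
  expect_lt(max(abs(pre$samples[iso_idx])), 0.05)

  # near idempotence of the baseline subtraction: once corrected, the
  # residual baseline the estimator finds is a few percent of the signal
  # (the FIR stage is excluded — re-smoothing an already smoothed QRS is
  # attenuation, not baseline correction)
  once <- correct_baseline(x, fs)
  again <- once - estimate_baseline(once, fs)
  expect_lt(sqrt(mean((again - once)^2)) / sqrt(mean(once^2)), 0.03)
})

test_that("mains notch removes 50 Hz but spares the diagnostic band", {
  fs <- 500
  tt <- (0:4999) / fs
  tone50 <- sin(2 * pi * 50 * tt)
  tone10 <- sin(2 * pi * 10 * tt)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(notch_50hz(tone50, fs)) / rms(tone50), 0.1)
  expect_gt(rms(notch_50hz(tone10, fs)) / rms(tone10), 0.89)
  expect_equal(notch_50hz(rep(0, 1000), fs), rep(0, 1000))
  out <- notch_50hz(rnorm(777), fs)
  expect_length(out, 777L)
  expect_true(all(is.finite(out)))
  expect_error(notch_50hz(tone50, 80), "too low")
})
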