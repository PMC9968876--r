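test_that("Butterworth design is validated and has unit DC gain", {
  co <- butter_lowpass(4, 35, 100)
  expect_equal(sum(co$b) / sum(co$a), 1, tolerance = 1e-12)
  expect_error(butter_lowpass(4, 60, 100), "0, rate/2", fixed = TRUE)
  expect_error(filter_spec(3, 20), "order")
})

test_that("zero-lag filtering preserves DC and has zero lag", {
  y <- lowpass_zero_lag(rep(1, 200), filter_spec(4, 35), 100)
  expect_equal(y, rep(1, 200), tolerance = 1e-9)

  t <- seq(0, 4, by = 0.01)
  x <- sin(2 * pi * 5 * t)
  y <- lowpass_zero_lag(x, filter_spec(4, 35), 100)
  cc <- stats::ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(lowpass_zero_lag(rep(1, 10), filter_spec(4, 35), 100),
               "too short")
})

test_that("two-pass attenuation matches the closed-form magnitude", {
  # probes far below Nyquist, where the analog closed form is valid
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  for (f in c(5, 20, 45)) {
    y <- lowpass_zero_lag(sin(2 * pi * f * t), filter_spec(4, 35), rate)
    got <- max(abs(y[1000:3000]))
    want <- 1 / (1 + (f / 35)^8)    # |H|^2 of a 4th-order design
    expect_lt(abs(got - want) / want, 0.02)
  }
})

test_that("resampling counts, DC and amplitude behave", {
  t <- (0:999) / 200
  out <- resample_to(rep(2.5, 1000), t, 100)
  expect_length(out$series, 500L)
  expect_equal(out$series, rep(2.5, 500), tolerance = 1e-9)

  x <- sin(2 * pi * 5 * t)
  out <- resample_to(x, t, 100)
  expect_lt(abs(max(abs(out$series[100:400])) - 1), 0.01)
  expect_error(resample_to(x, t, 400), "upsampling")
})

test_that("resampling preserves sub-35 Hz signal energy within 2%", {
  t <- (0:1999) / 200
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 20 * t)
  out <- resample_to(x, t, 100)
  # mean power is rate-independent for band-limited content
  p_in <- mean(x[200:1800]^2)
  p_out <- mean(out$series[100:900]^2)
  expect_lt(abs(p_out - p_in) / p_in, 0.02)
})
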