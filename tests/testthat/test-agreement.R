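test_that("waveform and stance RMSE match brute-force computation", {
  set.seed(4)
  m <- abs(rnorm(500)); e <- m + rnorm(500, 0, 0.2)
  expect_equal(waveform_rmse(m, m), 0)
  expect_equal(waveform_rmse(m, m + 0.1), 0.1)
  expect_equal(waveform_rmse(m, e), sqrt(sum((m - e)^2) / 500),
               tolerance = 1e-12)
  expect_error(waveform_rmse(m, e[-1]), "equal length")

  f <- numeric(300); f[51:80] <- 1; f[151:180] <- 1.2
  ev <- detect_stances(f, 100)
  expect_equal(stance_rmse(f, f, ev), 0)
  expect_equal(stance_rmse(f, f + 0.1, ev), 0.1)
  # brute-force oracle: mean over per-stance RMSEs
  e2 <- f + rnorm(300, 0, 0.1)
  oracle <- mean(c(sqrt(mean((f[51:80] - e2[51:80])^2)),
                   sqrt(mean((f[151:180] - e2[151:180])^2))))
  expect_equal(stance_rmse(f, e2, ev), oracle, tolerance = 1e-12)
})

test_that("event differences use the measured-minus-estimated convention", {
  f <- numeric(400); f[101:130] <- 1; f[201:230] <- 1; f[301:330] <- 1
  m_ev <- detect_stances(f, 100)
  e <- numeric(400); e[99:128] <- 1; e[199:228] <- 1; e[299:328] <- 1
  e_ev <- detect_stances(e, 100)    # estimate 0.02 s early
  d <- event_differences(m_ev, e_ev)
  expect_equal(d$ic_diffs, rep(0.02, 3))
  expect_equal(d$to_diffs, rep(0.02, 3))

  d0 <- event_differences(m_ev, m_ev)
  expect_true(all(d0$ic_diffs == 0) && all(d0$to_diffs == 0))

  d1 <- event_differences(m_ev, e_ev[1:2, ])
  expect_equal(d1$unpaired_measured, 1L)
  expect_equal(d1$unpaired_estimated, 0L)
})

test_that("Bland-Altman matches the hand-computed example", {
  ba <- bland_altman(c(1, 2, 3), c(1, 1, 1))
  expect_equal(ba$bias, 1.0)
  expect_equal(ba$loa_low, 1 - 1.96, tolerance = 1e-12)   # sd({0,1,2}) = 1
  expect_equal(ba$loa_high, 1 + 1.96, tolerance = 1e-12)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  swapped <- bland_altman(c(1, 1, 1), c(1, 2, 3))
  expect_equal(swapped$bias, -ba$bias)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("correlation bands label r-squared values correctly", {
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  r <- correlation_r2(y, x)
  expect_equal(r$r2, 1)
  expect_equal(r$label, "strong")
  expect_equal(r2_label(0.85), "strong")
  expect_equal(r2_label(0.795), "moderate")
  expect_equal(r2_label(0.405), "weak")
  expect_equal(r2_label(0.133), "negligible")
  expect_equal(correlation_r2(rep(1, 4), x)$label, "undefined")
})

test_that("regression CIs equal the textbook closed form", {
  set.seed(11)
  x <- 1:10; y <- 0.5 + 1.7 * x + rnorm(10, 0, 0.3)
  r <- agreement_regression(y, x)
  # closed-form OLS with t-based intervals
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  s2 <- sum((y - b0 - b1 * x)^2) / 8
  se1 <- sqrt(s2 / sum((x - mean(x))^2))
  tq <- qt(0.975, 8)
  expect_equal(r$slope, b1, tolerance = 1e-12)
  expect_equal(r$intercept, b0, tolerance = 1e-12)
  expect_equal(r$slope_ci, c(b1 - tq * se1, b1 + tq * se1),
               tolerance = 1e-10)
})

test_that("per-velocity summaries aggregate exactly and order-invariantly", {
  sim <- noiseless_trial(3.35, duration = 20)
  f <- sum_bilateral_force(sim$force)
  e <- pmax(f + 0.05 * sin(seq_along(f) / 7), 0)
  e[e < 0.05] <- 0
  rows <- rbind(
    trial_agreement(f, e, 100, "T1", 3.35),
    trial_agreement(f, e, 100, "T2", 3.35),
    trial_agreement(f, f, 100, "T3", 3.83))
  s <- per_velocity_summary(rows)
  expect_equal(nrow(s), 2L)
  expect_equal(s$stance_rmse_bw_sd[s$velocity == 3.35], 0)  # identical trials
  expect_equal(s$stance_rmse_bw_sd[s$velocity == 3.83], 0)  # single trial
  expect_equal(s$stance_rmse_bw_mean[s$velocity == 3.35],
               mean(rows$stance_rmse_bw[1:2]))
  expect_identical(per_velocity_summary(rows[c(3, 1, 2), ]), s)
  expect_equal(nrow(per_velocity_summary(rows[0, ])), 0L)

  va <- variable_agreement(rbind(rows, rows))
  expect_true(all(c("bias", "loa_low", "r2", "label") %in% names(va)))
})
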