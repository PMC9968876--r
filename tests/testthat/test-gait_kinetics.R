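test_that("stance detection follows the 5% BW first/last-instance rule", {
  f <- numeric(300)
  f[101:130] <- 1          # indices 101..130 -> 1.00 s .. 1.29 s
  ev <- detect_stances(f, 100)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ic_s, 1.00)
  expect_equal(ev$to_s, 1.29)
  expect_equal(contact_time(ev), 0.29)
  expect_equal(contact_time(ev), (ev$to_idx - ev$ic_idx) / 100)

  expect_warning(ev0 <- detect_stances(rep(0.04, 100), 100), "no stance")
  expect_equal(nrow(ev0), 0L)
})

test_that("half-sine closed forms: average, impulse, peak, loading rate", {
  rate <- 1000
  tc <- 0.3
  f <- half_sine_stance(tc = tc, rate = rate)
  n_pad <- 100L
  ev <- data.frame(ic_idx = n_pad + 1L, to_idx = n_pad + 301L,
                   ic_s = n_pad / rate, to_s = (n_pad + 300) / rate)
  k <- stance_kinetics(f, ev, rate, strategy = "fixed_window")
  expect_equal(k$stance_average_bw, 1.0, tolerance = 0.005)
  expect_equal(k$impulse_bw_s, 0.30, tolerance = 0.005)
  expect_equal(k$peak_bw, pi / 2, tolerance = 0.005)
  # no impact peak on a monotone rise to mid-stance
  expect_true(is.na(find_impact_peak(f, ev, rate)))
  # fixed-window slope between 10% and 40% of contact time, closed form
  Fs <- function(t) (pi / 2) * sin(pi * t / tc)
  want <- (Fs(0.12) - Fs(0.03)) / 0.09
  expect_equal(average_loading_rate(f, ev, rate, "fixed_window"), want,
               tolerance = 1e-3)
  # linearity: doubling force doubles the loading rate
  expect_equal(average_loading_rate(2 * f, ev, rate, "fixed_window"),
               2 * average_loading_rate(f, ev, rate, "fixed_window"))
})

test_that("constant stance has trivially exact kinetics", {
  rate <- 100
  f <- c(numeric(10), rep(1, 21), numeric(10))
  ev <- detect_stances(f, rate)
  k <- stance_kinetics(f, ev, rate, strategy = "fixed_window")
  expect_equal(k$stance_average_bw, 1)
  expect_equal(k$impulse_bw_s, 0.2)
  expect_equal(k$peak_bw, 1)
})

test_that("impact peak: planted bump found, first of two wins", {
  rate <- 1000
  tc <- 0.3
  t <- seq(0, tc, by = 1 / rate)
  base <- (pi / 2) * sin(pi * t / tc)
  bump <- function(c_frac, a) a * exp(-0.5 * ((t - c_frac * tc) / 0.004)^2)
  f1 <- c(numeric(50), base + bump(0.12, 0.4), numeric(50))
  ev <- detect_stances(f1, rate)
  tp <- find_impact_peak(f1, ev, rate)
  expect_lt(abs((tp - ev$ic_s) - 0.12 * tc), 0.005)

  f2 <- c(numeric(50), base + bump(0.10, 0.4) + bump(0.25, 0.4), numeric(50))
  ev2 <- detect_stances(f2, rate)
  tp2 <- find_impact_peak(f2, ev2, rate)
  expect_lt(abs((tp2 - ev2$ic_s) - 0.10 * tc), 0.005)

  # linear ramp to the impact peak: slope recovered exactly
  fr <- c(numeric(10), seq(0, 2, length.out = 6), seq(1.8, 2.5, length.out = 10),
          seq(2.5, 0, length.out = 25), numeric(10))
  evr <- detect_stances(fr, 100)
  expect_equal(average_loading_rate(fr, evr, 100), 40, tolerance = 1e-9)
})

test_that("estimate cleaning removes sub-0.050 s contacts only", {
  f <- numeric(400)
  f[101:103] <- c(0.4, 0.8, 0.4)   # 0.03 s contact
  f[201:225] <- 1                  # 0.25 s contact
  y <- postprocess_estimate(f, 100, filter = FALSE)
  expect_true(all(y[101:103] == 0))
  expect_true(all(y[201:225] > 0))
  expect_identical(postprocess_estimate(numeric(300), 100),
                   numeric(300))
})

test_that("kinetics are invariant to appended flight zeros and obey bounds", {
  sim <- noiseless_trial()
  f <- sum_bilateral_force(sim$force)
  k1 <- trial_kinetics(f, 100)
  k2 <- trial_kinetics(c(f, numeric(200)), 100)
  expect_equal(k1, k2[seq_len(nrow(k1)), ], ignore_attr = TRUE)
  expect_true(all(k1$stance_average_bw <= k1$peak_bw))
  expect_true(all(k1$impulse_bw_s >= 0 &
                    k1$impulse_bw_s <= k1$peak_bw * k1$contact_time_s))
})
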