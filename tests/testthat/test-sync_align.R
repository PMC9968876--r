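make_stomp_streams <- function(force_delay = 0) {
  t <- (0:999) / 100
  acc <- rep(9.81, 1000)
  acc[t >= 2.0 & t < 2.02] <- 60
  fbw <- numeric(1000)
  on <- t >= (2.0 + force_delay) & t < (2.06 + force_delay)
  fbw[on] <- 1.2
  list(t = t, acc = acc, fbw = fbw)
}

test_that("stomp detection recovers injected offsets within one sample", {
  s <- make_stomp_streams(0)
  r <- detect_stomp(s$acc, s$t, s$fbw, s$t)
  expect_lt(abs(r$offset_s), 0.011)

  s <- make_stomp_streams(0.37)
  r <- detect_stomp(s$acc, s$t, s$fbw, s$t)
  expect_equal(r$offset_s, 0.37, tolerance = 0.011)

  flat <- rep(9.81, 1000)
  expect_error(detect_stomp(flat, s$t, s$fbw, s$t), "sync error")
  expect_error(detect_stomp(s$acc, s$t, numeric(1000), s$t), "sync error")
})

test_that("foot-IMU IC detection recovers simulator ground truth", {
  sim <- noiseless_trial()
  imus <- simulate_imu(sim, seed = 2, noise_scale = 0)
  cfg <- pipeline_config()
  foot <- imugrf:::resample_filter_imu(imus$left_foot, cfg)
  ics <- detect_ic_from_imu(foot)
  truth <- sim$truth$ic_s[sim$truth$foot == "left"]
  expect_equal(length(ics), length(truth))
  expect_lt(max(abs(ics - truth)), 0.0101)

  # amplitude scale invariance
  foot2 <- foot
  foot2$accel <- foot2$accel * 2
  foot2$gyro <- foot2$gyro * 2
  expect_equal(detect_ic_from_imu(foot2), ics)

  flat <- foot
  flat$accel[] <- 0
  expect_error(detect_ic_from_imu(flat), "flat")
})

test_that("drift correction is a no-op without drift and is idempotent", {
  sim <- noiseless_trial()
  truth_ics <- sim$truth$ic_s
  r1 <- correct_clock_drift(sim$force, truth_ics)
  expect_equal(r1$report$samples_inserted + r1$report$samples_removed, 0)
  expect_identical(r1$force$force_left, sim$force$force_left)

  drifted <- inject_drift(sim$force, 200)
  r2 <- correct_clock_drift(drifted, truth_ics)
  r3 <- correct_clock_drift(r2$force, truth_ics)
  expect_identical(r3$force$force_left, r2$force$force_left)
  expect_equal(r3$report$samples_inserted + r3$report$samples_removed, 0)
})

test_that("drift edits preserve stance samples and impulses exactly", {
  sim <- noiseless_trial(duration = 60)
  drifted <- inject_drift(sim$force, 200)   # ~12 ms over 60 s
  # exaggerate: stretch timebase further via a second injection
  drifted <- inject_drift(drifted, 200)
  r <- correct_clock_drift(drifted, sim$truth$ic_s)
  expect_lte(r$report$max_residual_s, 0.02)
  stance_chunks <- function(f) {
    s <- (f$force_left + f$force_right) / f$body_weight
    runs <- imugrf:::contiguous_runs(s > 0.05)
    lapply(seq_len(nrow(runs)), function(i)
      s[runs$start[i]:runs$end[i]])
  }
  expect_identical(stance_chunks(drifted), stance_chunks(r$force))
})

test_that("unpairable ICs raise an alignment error listing orphans", {
  sim <- noiseless_trial()
  expect_error(correct_clock_drift(sim$force, sim$truth$ic_s + 0.2),
               "alignment error")
  expect_error(correct_clock_drift(sim$force, sim$truth$ic_s[-1]),
               "alignment error")
})

test_that("per-foot IC lists merge with deduplication", {
  expect_equal(merge_ic_lists(c(1, 2), c(1.02, 2.5)),
               c(1.01, 2, 2.5))
  expect_equal(merge_ic_lists(numeric(0), 3), 3)
})
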