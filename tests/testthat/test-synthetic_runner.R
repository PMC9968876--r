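test_that("pace conversion matches the published pace ladder", {
  expect_equal(round(pace_to_velocity("8:00"), 2), 3.35)
  expect_equal(round(pace_to_velocity("7:00"), 2), 3.83)
  expect_equal(round(pace_to_velocity("8:30"), 2), 3.16)
  expect_equal(pace_to_velocity(1609.34 / 60), 1.0)    # definition
  expect_error(pace_to_velocity("0:00"), "positive")
})

test_that("profiles reject walking configurations", {
  expect_error(runner_profile(tc_a = 0.9, tc_b = 0), "walking")
  expect_error(runner_profile(mass_kg = -1), "positive")
})

test_that("stride-averaged summed force is 1 BW and duty factor < 0.5", {
  for (v in c(2.33, 3.35, 5.36)) {
    sim <- simulate_force(runner_profile(), v, 30, seed = 1,
                          noise_scale = 0)
    tr <- sim$truth
    f <- sim$force
    sum_bw <- (f$force_left + f$force_right) / f$body_weight
    i0 <- which.min(abs(f$time - tr$ic_s[1]))
    i1 <- which.min(abs(f$time - tr$ic_s[nrow(tr) - 1]))
    expect_equal(mean(sum_bw[i0:(i1 - 1)]), 1.0, tolerance = 0.01)
    tc <- sim$steps$tc[1]
    t_stride <- 2 * diff(sim$steps$ic[1:2])   # per-leg stride time
    expect_lt(tc / t_stride, 0.5)             # duty factor: running

    # flight phase: exact zeros exist between steps
    expect_gt(sum(sum_bw == 0), 0)
  }
})

test_that("contact time decreases with velocity and events are recovered", {
  tcs <- vapply(c(2.33, 2.98, 3.57, 4.47, 5.36), function(v)
    simulate_force(runner_profile(), v, 12, seed = 1,
                   noise_scale = 0)$steps$tc[1], numeric(1))
  expect_true(all(diff(tcs) < 0))

  sim <- noiseless_trial(3.35)
  expect_equal(sim$steps$tc[1], 0.38 - 0.03 * 3.35, tolerance = 1e-9)
  ev <- detect_stances(sum_bilateral_force(sim$force), 100)
  tr <- sim$truth
  expect_equal(nrow(ev), nrow(tr))
  expect_lt(max(abs(ev$ic_s - tr$ic_s)), 0.0101)
  expect_lt(max(abs(ev$to_s - tr$to_s)), 0.0101)
})

test_that("ground-truth kinetics match waveform kinetics at 100 Hz", {
  sim <- noiseless_trial(3.35)
  k <- trial_kinetics(sum_bilateral_force(sim$force), 100)
  tr <- sim$truth
  expect_equal(nrow(k), nrow(tr))
  expect_lt(max(abs(k$peak_bw - tr$peak_bw) / tr$peak_bw), 0.01)
  expect_lt(max(abs(k$impulse_bw_s - tr$impulse_bw_s) / tr$impulse_bw_s),
            0.02)
  expect_lt(max(abs(k$stance_average_bw - tr$stance_average_bw) /
                  tr$stance_average_bw), 0.03)
  # loading rate inherits event quantization at 100 Hz; see vignette
  expect_lt(max(abs(k$loading_rate_bw_s - tr$loading_rate_bw_s) /
                  tr$loading_rate_bw_s), 0.12)
})

test_that("sacrum acceleration is the stated affine image of summed force", {
  sim <- noiseless_trial(3.35)
  imus <- simulate_imu(sim, seed = 1, noise_scale = 0)
  az <- imus$sacrum$accel[, 3]
  t <- imus$sacrum$time
  # flight instants read -1 g
  flight <- which(imugrf:::force_bw_at(sim$steps, t) == 0)
  expect_equal(unique(az[flight]), -9.81)
  fbw <- imugrf:::force_bw_at(sim$steps, t)
  expect_equal(az, (fbw - 1) * 9.81, tolerance = 1e-9)
})

test_that("drift injection scales timestamps only", {
  sim <- noiseless_trial()
  d0 <- inject_drift(sim$force, 0)
  expect_identical(d0$time, sim$force$time)
  d <- inject_drift(sim$force, 50)
  expect_identical(d$force_left, sim$force$force_left)
  t_end <- 480
  expect_equal(t_end * (1 + 50e-6) - t_end, 0.024, tolerance = 1e-9)
  expect_equal(max(d$time) - max(sim$force$time),
               max(sim$force$time) * 50e-6)
  expect_error(inject_drift(sim$force, 500), "-200, 200")
})

test_that("cohort simulation is deterministic and pipeline-readable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- simulate_cohort(2, paces = "8:00", duration_s = 12, seed = 9,
                        out_dir = d1, noise_scale = 0, stomp = FALSE)
  m2 <- simulate_cohort(2, paces = "8:00", duration_s = 12, seed = 9,
                        out_dir = d2, noise_scale = 0, stomp = FALSE)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  gt <- utils::read.csv(file.path(d1, "ground_truth.csv"))
  expect_true(all(c("trial_id", "step", "ic_s", "peak_bw") %in% names(gt)))
  man <- read_manifest(m1[1])
  expect_length(load_manifest_trials(man, d1), 1L)
})
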