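#' Synthetic runner profile
#'
#' Parameters of the forward model for one simulated participant. Contact
#' time shortens and step frequency rises linearly with running velocity,
#' the dominant trends in overground running; coefficients default to
#' values typical of recreational runners (contact ~0.28 s and step
#' frequency ~2.9 Hz at 3.35 m s^-1).
#'
#' @param participant_id Identifier string.
#' @param mass_kg Body mass, kg.
#' @param tc_a,tc_b Contact-time model `Tc(v) = tc_a - tc_b * v` (s, and
#'   s per m s^-1).
#' @param sf_c,sf_d Step-frequency model `f(v) = sf_c + sf_d * v` (Hz,
#'   and Hz per m s^-1); steps alternate feet, so each foot strikes at
#'   `f/2`.
#' @param impact_amplitude_bw Amplitude of the early Gaussian impact bump
#'   added to the active half-sine, BW (0 disables it).
#' @param impact_center_frac Bump center as a fraction of stance (0.13).
#' @param impact_width_frac Bump standard deviation as a fraction of
#'   contact time.
#' @param accel_noise_sd,gyro_noise_sd Additive white sensor noise, m s^-2
#'   and rad s^-1.
#' @param force_noise_bw Additive noise on active force samples, BW.
#' @param drift_ppm Insole clock drift relative to the IMU clock, parts
#'   per million.
#' @return An object of class `runner_profile`.
#' @export
runner_profile <- function(participant_id = "P01", mass_kg = 73.5,
                           tc_a = 0.38, tc_b = 0.03,
                           sf_c = 2.5, sf_d = 0.12,
                           impact_amplitude_bw = 0.25,
                           impact_center_frac = 0.13,
                           impact_width_frac = 0.04,
                           accel_noise_sd = 0.4, gyro_noise_sd = 0.08,
                           force_noise_bw = 0.01,
                           drift_ppm = 0) {
  if (mass_kg <= 0) stop("mass_kg must be positive", call. = FALSE)
  p <- structure(as.list(environment()), class = "runner_profile")
  for (v in c(2.0, 6.0)) {
    tc <- tc_a - tc_b * v
    if (tc <= 0.05)
      stop("contact-time model degenerate at v = ", v, call. = FALSE)
    if (tc >= 1 / (sf_c + sf_d * v))
      stop("no flight phase at v = ", v,
           " m/s: profile describes walking, not running", call. = FALSE)
  }
  p
}

#' Convert a minutes-per-mile pace to velocity
#'
#' @param pace Pace as `"M:SS"` minutes per mile (e.g. `"8:00"`), or a
#'   numeric number of minutes per mile.
#' @return Average velocity, m s^-1 (1609.34 m per mile).
#' @export
pace_to_velocity <- function(pace) {
  if (is.character(pace)) {
    parts <- strsplit(pace, ":", fixed = TRUE)
    mins <- vapply(parts, function(p) {
      if (!length(p) %in% 1:2 || anyNA(suppressWarnings(as.numeric(p))))
        stop("malformed pace: ", paste(p, collapse = ":"), call. = FALSE)
      as.numeric(p[1]) + if (length(p) == 2) as.numeric(p[2]) / 60 else 0
    }, numeric(1))
  } else mins <- as.numeric(pace)
  if (any(mins <= 0)) stop("pace must be positive", call. = FALSE)
  1609.34 / (mins * 60)
}

# continuous summed force model, BW; steps is the per-step parameter table
step_schedule <- function(profile, velocity, duration_s, run_start, run_end) {
  tc <- profile$tc_a - profile$tc_b * velocity
  f_step <- profile$sf_c + profile$sf_d * velocity
  t_step <- 1 / f_step
  if (tc >= t_step)
    stop("no flight phase at this velocity; walking is not modeled",
         call. = FALSE)
  # Gaussian bump integral, used to keep the stride-average at 1 BW
  i_bump <- profile$impact_amplitude_bw * profile$impact_width_frac * tc *
    sqrt(2 * pi)
  amp <- (pi / 2) * (t_step - i_bump) / tc
  ics <- seq(run_start, run_end - tc, by = t_step)
  if (length(ics) < 2) stop("duration too short for gait", call. = FALSE)
  data.frame(foot = rep_len(c("left", "right"), length(ics)),
             ic = ics, tc = tc, amp = amp,
             bump_amp = profile$impact_amplitude_bw,
             bump_c = profile$impact_center_frac * tc,
             bump_sd = profile$impact_width_frac * tc)
}

# evaluate one step's continuous force (BW) at times t
step_force_at <- function(st, t) {
  ph <- t - st$ic
  active <- ph >= 0 & ph <= st$tc
  y <- numeric(length(t))
  y[active] <- st$amp * sin(pi * ph[active] / st$tc) +
    st$bump_amp * exp(-0.5 * ((ph[active] - st$bump_c) / st$bump_sd)^2)
  y
}

force_bw_at <- function(steps, t, feet = c("left", "right")) {
  y <- numeric(length(t))
  for (i in seq_len(nrow(steps))) {
    st <- steps[i, ]
    if (!st$foot %in% feet) next
    lo <- findInterval(st$ic, t); hi <- findInterval(st$ic + st$tc, t) + 1L
    idx <- max(1L, lo):min(length(t), hi)
    y[idx] <- y[idx] + step_force_at(st, t[idx])
  }
  y
}

# analytic-by-construction per-step truth on a fine grid
step_ground_truth <- function(steps, fine_rate = 2000, bw_threshold = 0.05) {
  out <- lapply(seq_len(nrow(steps)), function(i) {
    st <- steps[i, ]
    t <- seq(st$ic - 0.05, st$ic + st$tc + 0.05, by = 1 / fine_rate)
    y <- step_force_at(st, t)
    on_idx <- which(y > bw_threshold)
    ev <- data.frame(ic_idx = on_idx[1], to_idx = on_idx[length(on_idx)],
                     ic_s = (on_idx[1] - 1) / fine_rate,
                     to_s = (on_idx[length(on_idx)] - 1) / fine_rate)
    lr <- average_loading_rate(y, ev, fine_rate)
    span <- y[ev$ic_idx:ev$to_idx]
    data.frame(foot = st$foot,
               ic_s = t[ev$ic_idx], to_s = t[ev$to_idx],
               contact_time_s = t[ev$to_idx] - t[ev$ic_idx],
               peak_bw = max(span),
               stance_average_bw = mean(span),
               impulse_bw_s = sum((span[-1] + span[-length(span)]) / 2) /
                 fine_rate,
               loading_rate_bw_s = lr)
  })
  do.call(rbind, out)
}

#' Simulate an insole force recording
#'
#' Generates a running trial: per step the active force is a half-sine
#' `A sin(pi t / Tc)` with `A` chosen so that the stride-averaged summed
#' force equals 1 BW (impulse-momentum constraint for level running),
#' plus an optional Gaussian impact bump early in stance. Left and right
#' feet alternate with a half-stride offset; flight-phase force is
#' exactly 0. Ground-truth events and kinetics are evaluated on a 2000 Hz
#' grid of the continuous model, so they are consistent with the emitted
#' waveform by construction.
#'
#' @param profile A [runner_profile()].
#' @param velocity Average running velocity, m s^-1.
#' @param duration_s Trial duration, s (>= 10).
#' @param rate Insole sampling rate, Hz (default 100).
#' @param seed Integer seed for the sensor-noise RNG.
#' @param noise_scale Multiplier on the profile's noise levels (0 gives a
#'   noiseless trial).
#' @param stomp Add a synchronization foot stomp during the pre-run quiet
#'   period (default FALSE).
#' @param quiet_s Pre-run quiet period, s (stomp occurs at its midpoint).
#' @return List of class `runner_sim` with `force` (a
#'   [force_recording()]), `truth` (per-step data.frame), `steps`
#'   (internal step schedule), `velocity`, `stomp_time` (or NA), `profile`.
#' @export
simulate_force <- function(profile, velocity, duration_s, rate = 100,
                           seed = 1, noise_scale = 1, stomp = FALSE,
                           quiet_s = if (stomp) 4 else 0.5) {
  stopifnot(inherits(profile, "runner_profile"))
  if (duration_s < 10) stop("duration must be at least 10 s", call. = FALSE)
  run_start <- quiet_s + 0.2
  run_end <- duration_s - 0.3
  steps <- step_schedule(profile, velocity, duration_s, run_start, run_end)
  t <- seq(0, duration_s, by = 1 / rate)
  bw <- profile$mass_kg * GRAVITY
  fl <- force_bw_at(steps, t, "left")
  fr <- force_bw_at(steps, t, "right")
  stomp_time <- NA_real_
  if (stomp) {
    stomp_time <- quiet_s / 2
    ph <- t - stomp_time
    on <- ph >= 0 & ph <= 0.06
    fl[on] <- fl[on] + 1.5 * sin(pi * ph[on] / 0.06)
  }
  set.seed(seed)
  if (noise_scale > 0 && profile$force_noise_bw > 0) {
    sd <- noise_scale * profile$force_noise_bw
    fl[fl > 0] <- pmax(fl[fl > 0] + stats::rnorm(sum(fl > 0), 0, sd), 0)
    fr[fr > 0] <- pmax(fr[fr > 0] + stats::rnorm(sum(fr > 0), 0, sd), 0)
  }
  force <- force_recording(t, fl * bw, fr * bw, rate, bw)
  structure(list(force = force, truth = step_ground_truth(steps),
                 steps = steps, velocity = velocity,
                 duration_s = duration_s, stomp_time = stomp_time,
                 quiet_s = quiet_s, profile = profile),
            class = "runner_sim")
}

#' Simulate the three IMU recordings paired with a force simulation
#'
#' The sacrum vertical acceleration is an exact affine image of the
#' summed force before noise, `az = (F_bw - 1) * 9.81` m s^-2 (so during
#' flight it reads -9.81), which guarantees the inertial-to-force mapping
#' is learnable. Foot sensors carry a decaying-oscillation impact
#' transient after each ipsilateral initial contact, a sinusoidal swing
#' signature, and a sagittal-plane gyro dip whose minimum falls exactly
#' at initial contact (the cue the alignment IC detector uses). Values
#' are clipped at the +/-16 g range of the modeled device.
#'
#' @param sim A `runner_sim` from [simulate_force()].
#' @param rate IMU sampling rate, Hz (default 200).
#' @param seed Integer seed for sensor noise.
#' @param noise_scale Multiplier on profile noise levels.
#' @return Named list of three [imu_recording()]s
#'   (`left_foot`, `right_foot`, `sacrum`).
#' @export
simulate_imu <- function(sim, rate = 200, seed = 1, noise_scale = 1) {
  stopifnot(inherits(sim, "runner_sim"))
  profile <- sim$profile
  t <- seq(0, sim$duration_s, by = 1 / rate)
  n <- length(t)
  clip <- 16 * GRAVITY
  set.seed(seed + 1L)
  f_step <- profile$sf_c + profile$sf_d * sim$velocity
  stride_hz <- f_step / 2

  noise <- function(sd) if (noise_scale > 0 && sd > 0)
    stats::rnorm(n, 0, noise_scale * sd) else numeric(n)

  stomp_pulse <- function() {
    y <- numeric(n)
    if (!is.na(sim$stomp_time))
      y <- 90 * exp(-0.5 * ((t - sim$stomp_time) / 0.005)^2)
    y
  }

  foot_rec <- function(side) {
    ics <- sim$truth$ic_s[sim$truth$foot == side]
    # the stomp behaves like an extra contact on both feet, so the IC
    # detector can anchor it during alignment
    if (!is.na(sim$stomp_time)) ics <- c(sim$stomp_time, ics)
    az <- rep(-GRAVITY, n)
    gy <- 2.0 * sin(2 * pi * stride_hz * t)
    for (ic in ics) {
      ph <- t - ic
      w <- ph >= 0 & ph < 0.15
      az[w] <- az[w] + 60 * exp(-ph[w] / 0.03) * sin(2 * pi * 12 * ph[w])
      gy <- gy - 8 * exp(-0.5 * ((t - ic) / 0.015)^2)
    }
    ax <- 1.5 * sin(2 * pi * stride_hz * t + ifelse(side == "left", 0, pi)) +
      noise(profile$accel_noise_sd)
    ay <- 1.0 * cos(2 * pi * stride_hz * t) + noise(profile$accel_noise_sd)
    az <- az + stomp_pulse() + noise(profile$accel_noise_sd)
    gx <- 0.5 * sin(2 * pi * stride_hz * t) + noise(profile$gyro_noise_sd)
    gz <- 0.3 * cos(2 * pi * stride_hz * t) + noise(profile$gyro_noise_sd)
    gy <- gy + noise(profile$gyro_noise_sd)
    accel <- pmin(pmax(cbind(ax, ay, az), -clip), clip)
    imu_recording(paste0(side, "_foot"), t, accel, cbind(gx, gy, gz), rate)
  }

  left <- foot_rec("left")
  right <- foot_rec("right")

  fbw <- force_bw_at(sim$steps, t)
  if (!is.na(sim$stomp_time)) {
    ph <- t - sim$stomp_time
    on <- ph >= 0 & ph <= 0.06
    fbw[on] <- fbw[on] + 1.5 * sin(pi * ph[on] / 0.06)
  }
  az <- (fbw - 1) * GRAVITY + noise(profile$accel_noise_sd)
  ax <- 0.8 * sin(2 * pi * f_step * t) + noise(profile$accel_noise_sd)
  ay <- 0.5 * cos(2 * pi * f_step * t) + noise(profile$accel_noise_sd)
  az <- az + stomp_pulse()
  accel <- pmin(pmax(cbind(ax, ay, az), -clip), clip)
  gyro <- cbind(0.3 * sin(2 * pi * f_step * t) + noise(profile$gyro_noise_sd),
                0.2 * cos(2 * pi * f_step * t) + noise(profile$gyro_noise_sd),
                noise(profile$gyro_noise_sd))
  sacrum <- imu_recording("sacrum", t, accel, gyro, rate)

  list(left_foot = left, right_foot = right, sacrum = sacrum)
}

#' Inject clock drift into a recording
#'
#' Scales the recording's timestamps by `1 + drift_ppm * 1e-6`, emulating
#' a sensor whose internal clock runs fast or slow; data values are
#' untouched.
#'
#' @param recording An [imu_recording()] or [force_recording()].
#' @param drift_ppm Clock drift in parts per million, within [-200, 200].
#' @return The recording with scaled timestamps.
#' @export
inject_drift <- function(recording, drift_ppm) {
  if (abs(drift_ppm) > 200)
    stop("drift_ppm outside the modeled [-200, 200] range", call. = FALSE)
  recording$time <- recording$time * (1 + drift_ppm * 1e-6)
  recording
}

#' Simulate a cohort and write it to disk
#'
#' Draws participant profiles from seeded distributions over ranges
#' typical of a recreational-to-trained running cohort (mass 54-82 kg),
#' simulates every (participant, pace) trial, and writes the IMU CSVs,
#' insole CSVs, a `ground_truth.csv` and one manifest per participant
#' under `out_dir`. Trials include a synchronization foot stomp, and the
#' insole recording carries the participant's clock drift, so the full
#' preprocessing chain is exercised.
#'
#' @param n_participants Number of participants (>= 2).
#' @param paces Character vector of minutes-per-mile pace labels shared
#'   by all participants (default the 8:30-6:30 ladder).
#' @param duration_s Trial duration, s (default 120, roughly a 400 m
#'   repeat at these paces).
#' @param seed Master integer seed; everything downstream derives from it.
#' @param out_dir Output directory (created if needed).
#' @param noise_scale Multiplier on all sensor noise (0 = noiseless).
#' @param drift_range Range of per-participant insole clock drift, ppm.
#' @param stomp Include the sync stomp (default TRUE).
#' @return Character vector of manifest paths, invisibly; attribute
#'   `"n_trials"` carries the total trial count.
#' @export
simulate_cohort <- function(n_participants, paces = c("8:30", "8:00", "7:30",
                                                      "7:00", "6:30"),
                            duration_s = 120, seed = 1,
                            out_dir = tempfile("cohort"), noise_scale = 1,
                            drift_range = c(-50, 50), stomp = TRUE) {
  if (n_participants < 2)
    stop("need at least 2 participants", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  velocities <- pace_to_velocity(paces)
  set.seed(seed)
  masses <- stats::runif(n_participants, 54, 82)
  tc_as <- stats::rnorm(n_participants, 0.38, 0.008)
  sf_cs <- stats::rnorm(n_participants, 2.5, 0.05)
  drifts <- stats::runif(n_participants, drift_range[1], drift_range[2])
  manifest_paths <- character(n_participants)
  truth_rows <- list()
  n_trials <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    prof <- runner_profile(pid, mass_kg = masses[p], tc_a = tc_as[p],
                           sf_c = sf_cs[p], drift_ppm = drifts[p])
    trials <- list()
    for (k in seq_along(paces)) {
      trial_id <- sprintf("%s_T%d", pid, k)
      tseed <- (seed * 1000L + p * 100L + k) %% .Machine$integer.max
      sim <- simulate_force(prof, velocities[k], duration_s, seed = tseed,
                            noise_scale = noise_scale, stomp = stomp)
      imus <- simulate_imu(sim, seed = tseed, noise_scale = noise_scale)
      force_drifted <- inject_drift(sim$force, prof$drift_ppm)
      fpath <- file.path(out_dir, paste0(trial_id, "_force.csv"))
      write_force_csv(force_drifted, fpath)
      ipaths <- c(left_foot = paste0(trial_id, "_lfoot.csv"),
                  right_foot = paste0(trial_id, "_rfoot.csv"),
                  sacrum = paste0(trial_id, "_sacrum.csv"))
      for (s in names(ipaths))
        write_imu_csv(imus[[s]], file.path(out_dir, ipaths[[s]]))
      trials[[k]] <- list(trial_id = trial_id, pace_label = paces[k],
                          target_velocity = round(velocities[k], 2),
                          imu_paths = ipaths,
                          force_path = basename(fpath))
      truth_rows[[trial_id]] <- cbind(trial_id = trial_id,
                                      step = seq_len(nrow(sim$truth)),
                                      sim$truth)
      n_trials <- n_trials + 1L
    }
    man <- list(participant_id = pid, mass_kg = masses[p], seed = seed,
                trials = trials)
    manifest_paths[p] <- file.path(out_dir, paste0(pid, "_manifest.txt"))
    write_manifest(man, manifest_paths[p])
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth[, c("trial_id", "step", "foot", "ic_s", "to_s",
                             "peak_bw", "impulse_bw_s", "loading_rate_bw_s")],
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(structure(manifest_paths, n_trials = n_trials))
}

#' Merge per-foot IC lists into one bilateral sequence
#'
#' Concatenates and sorts IC times from the two foot sensors, collapsing
#' detections closer than `min_gap` seconds (e.g. the sync stomp, seen by
#' both feet) to their mean.
#'
#' @param ... Numeric vectors of IC times.
#' @param min_gap Merge tolerance, s (default 0.1).
#' @return Sorted numeric vector.
#' @export
merge_ic_lists <- function(..., min_gap = 0.1) {
  x <- sort(c(...))
  if (length(x) < 2) return(x)
  grp <- cumsum(c(1, diff(x) > min_gap))
  as.numeric(tapply(x, grp, mean))
}
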