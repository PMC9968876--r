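#' Detect the synchronization foot stomp
#'
#' Trials begin with a foot stomp recorded by both sensor systems. The
#' stomp is located as the acceleration-magnitude peak in the IMU stream
#' and the first rise of the summed force above 5% BW in the insole
#' stream, both within the first `window_s` seconds; the offset between
#' the two clocks is their time difference.
#'
#' @param imu_accel_mag Acceleration magnitude, m s^-2.
#' @param imu_time IMU timestamps, s.
#' @param force_bw Summed insole force, BW.
#' @param force_time Force timestamps, s.
#' @param window_s Search window from the start of each stream (default 10).
#' @param bw_threshold Force rise threshold, BW (default 0.05).
#' @return List of class `sync_result`: `offset_s` (force clock minus IMU
#'   clock), `stomp_time_imu`, `stomp_time_force`.
#' @export
detect_stomp <- function(imu_accel_mag, imu_time, force_bw, force_time,
                         window_s = 10, bw_threshold = 0.05) {
  wi <- imu_time <= imu_time[1] + window_s
  wf <- force_time <= force_time[1] + window_s
  dev <- abs(imu_accel_mag[wi] - stats::median(imu_accel_mag[wi]))
  thr <- 3 * stats::mad(imu_accel_mag[wi])
  if (max(dev) <= max(thr, 1e-6))
    stop("sync error: no acceleration transient above 3x baseline MAD ",
         "in the first ", window_s, " s", call. = FALSE)
  stomp_imu <- imu_time[wi][which.max(dev)]
  rise <- which(force_bw[wf] > bw_threshold)
  if (length(rise) == 0)
    stop("sync error: no force rise above ", bw_threshold,
         " BW in the first ", window_s, " s", call. = FALSE)
  stomp_force <- force_time[wf][rise[1]]
  offset <- stomp_force - stomp_imu
  if (abs(offset) >= 5)
    stop("sync error: implausible offset ", round(offset, 3), " s",
         call. = FALSE)
  structure(list(offset_s = offset, stomp_time_imu = stomp_imu,
                 stomp_time_force = stomp_force),
            class = "sync_result")
}

#' Detect initial contacts from a foot IMU
#'
#' Heuristic foot-worn-IMU IC detector used only to drive clock-drift
#' correction (never for reported kinetics): each resultant-acceleration
#' impact peak is located, and the IC is placed at the minimum of the
#' sagittal-plane angular velocity in the 0.12 s preceding the peak --
#' the characteristic pre-contact swing reversal of the foot.
#'
#' @param foot_imu An [imu_recording()] (or list with `accel`, `gyro`,
#'   `time`) already resampled to 100 Hz and low-pass filtered.
#' @param rate Sampling rate, Hz (default 100).
#' @param min_separation_s Minimum spacing between impact peaks, s.
#' @param rel_threshold Peaks must exceed this fraction of the 99th
#'   percentile of the baseline-corrected magnitude excursion (a quantile
#'   rather than the maximum, so one oversized transient such as the sync
#'   stomp does not mask ordinary impact peaks).
#' @return Numeric vector of IC times, s.
#' @export
detect_ic_from_imu <- function(foot_imu, rate = 100, min_separation_s = 0.35,
                               rel_threshold = 0.4) {
  mag <- sqrt(rowSums(foot_imu$accel^2))
  time <- foot_imu$time
  dev <- mag - stats::median(mag)
  if (max(dev) <= 1e-9)
    stop("IC detection error: flat acceleration magnitude", call. = FALSE)
  thr <- rel_threshold * stats::quantile(dev, 0.99, names = FALSE)
  n <- length(dev)
  cand <- which(dev > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[dev[cand] >= dev[cand - 1] & dev[cand] > dev[cand + 1]]
  # enforce minimum separation, keeping the larger peak
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && time[i] - time[peaks[length(peaks)]] <
          min_separation_s) {
      if (dev[i] > dev[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else peaks <- c(peaks, i)
  }
  gy <- foot_imu$gyro[, 2]
  ics <- vapply(peaks, function(p) {
    lo <- max(1L, p - as.integer(round(0.12 * rate)))
    time[lo:p][which.min(gy[lo:p])]
  }, numeric(1))
  span <- diff(range(time))
  if (span > 10 && length(ics) < 2)
    stop("IC detection error: fewer than 2 events in a ",
         round(span), " s trial", call. = FALSE)
  ics
}

# maximal zero-force runs of the summed sample array
zero_runs <- function(sum_force) contiguous_runs(sum_force == 0)

#' Iterative clock-drift correction
#'
#' Residual drift between the insole and IMU clocks is removed the way
#' the measurement chain motivates: the force stream is re-stamped onto
#' its nominal uniform grid and zero-valued samples are inserted into or
#' removed from the swing (zero-force) interval preceding each initial
#' contact whose residual against the paired IMU-detected IC exceeds
#' `tol`. Edits never touch a stance-phase sample, so per-step impulses
#' are bit-invariant, and the sweep is idempotent.
#'
#' @param force A [force_recording()] (timestamps may carry drift; they
#'   are replaced by the nominal uniform grid).
#' @param imu_ics IC times from [detect_ic_from_imu()], s (IMU clock,
#'   assumed the reference after stomp synchronization).
#' @param force_ics Optional pre-computed force IC times; detected from
#'   the waveform when `NULL`.
#' @param tol Residual tolerance, s (default 0.02).
#' @param pair_tol Maximum IC pairing distance, s (default 0.1).
#' @param bw_threshold Stance threshold, BW.
#' @return List: `force` (corrected recording) and `report` (class
#'   `drift_report`: data.frame `ic_pairs` with per-pair residuals and
#'   edits, plus `max_residual_s`, `samples_inserted`, `samples_removed`).
#' @export
correct_clock_drift <- function(force, imu_ics, force_ics = NULL,
                                tol = 0.02, pair_tol = 0.1,
                                bw_threshold = 0.05) {
  stopifnot(inherits(force, "force_recording"))
  # work in the recording's own timebase: a drifting clock shows up as a
  # timestep slightly off nominal, and the discrete edit mechanism must
  # operate on that grid, not on the nominal one
  dt <- stats::median(diff(force$time))
  rate <- 1 / dt
  t0 <- force$time[1]
  fl <- force$force_left
  fr <- force$force_right
  sum_bw <- (fl + fr) / force$body_weight
  ic_idx_of <- function(sum_bw) {
    runs <- contiguous_runs(sum_bw > bw_threshold)
    runs$start
  }
  fic <- ic_idx_of(sum_bw)
  fic_t <- t0 + (fic - 1) / rate
  if (!is.null(force_ics)) {
    # caller-supplied ICs are matched to detected ones; unknowns are an error
    if (length(force_ics) != length(fic_t) ||
        max(abs(force_ics - fic_t)) > pair_tol)
      stop("alignment error: supplied force ICs disagree with waveform",
           call. = FALSE)
  }
  imu_ics <- sort(imu_ics)
  # greedy nearest-time pairing in temporal order
  used <- logical(length(fic))
  pair_f <- integer(0); pair_i <- integer(0)
  orphans_imu <- numeric(0)
  for (j in seq_along(imu_ics)) {
    d <- abs(fic_t - imu_ics[j])
    d[used] <- Inf
    k <- which.min(d)
    if (!length(k) || d[k] > pair_tol) {
      orphans_imu <- c(orphans_imu, imu_ics[j])
    } else {
      used[k] <- TRUE
      pair_f <- c(pair_f, k); pair_i <- c(pair_i, j)
    }
  }
  orphans_force <- fic_t[!used]
  if (length(orphans_imu) || length(orphans_force))
    stop("alignment error: unpairable ICs (imu: ",
         paste(round(orphans_imu, 3), collapse = ", "),
         "; force: ", paste(round(orphans_force, 3), collapse = ", "), ")",
         call. = FALSE)
  ord <- order(pair_f)
  pair_f <- pair_f[ord]; pair_i <- pair_i[ord]

  inserted <- 0L; removed <- 0L
  edits <- integer(length(pair_f))
  for (jj in seq_along(pair_f)) {
    k <- pair_f[jj]
    res <- (t0 + (fic[k] - 1) / rate) - imu_ics[pair_i[jj]]
    if (abs(res) <= tol) next
    n_edit <- as.integer(round(res * rate))   # >0: force IC late, remove
    zr <- zero_runs(sum_bw)
    zr <- zr[zr$end < fic[k], , drop = FALSE]
    if (nrow(zr) == 0)
      stop("alignment error: no swing interval before IC at ",
           round(t0 + (fic[k] - 1) / rate, 3), " s", call. = FALSE)
    run <- zr[nrow(zr), ]
    len <- run$end - run$start + 1L
    mid <- run$start + len %/% 2L
    if (n_edit > 0) {
      n_rm <- min(n_edit, len - 2L)
      if (n_rm < 1L)
        stop("alignment error: swing interval too short to edit before IC at ",
             round(t0 + (fic[k] - 1) / rate, 3), " s", call. = FALSE)
      keep <- setdiff(seq_along(fl),
                      (mid - n_rm %/% 2L):(mid - n_rm %/% 2L + n_rm - 1L))
      fl <- fl[keep]; fr <- fr[keep]; sum_bw <- sum_bw[keep]
      removed <- removed + n_rm
      fic <- ic_idx_of(sum_bw)
      edits[jj] <- -n_rm
    } else {
      n_in <- -n_edit
      fl <- append(fl, rep(0, n_in), after = mid)
      fr <- append(fr, rep(0, n_in), after = mid)
      sum_bw <- append(sum_bw, rep(0, n_in), after = mid)
      inserted <- inserted + n_in
      fic <- ic_idx_of(sum_bw)
      edits[jj] <- n_in
    }
  }
  fic_t <- t0 + (fic - 1) / rate
  residuals <- fic_t[pair_f] - imu_ics[pair_i]
  out <- force_recording(t0 + (seq_along(fl) - 1) / rate, fl, fr, rate,
                         force$body_weight)
  report <- structure(list(
    ic_pairs = data.frame(imu_ic_s = imu_ics[pair_i],
                          force_ic_s = fic_t[pair_f],
                          residual_s = residuals, edits = edits),
    max_residual_s = if (length(residuals)) max(abs(residuals)) else 0,
    samples_inserted = inserted, samples_removed = removed),
    class = "drift_report")
  list(force = out, report = report)
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf(paste0("<drift_report> %d IC pairs, max |residual| %.4f s, ",
                     "+%d/-%d samples\n"),
              nrow(x$ic_pairs), x$max_residual_s,
              x$samples_inserted, x$samples_removed))
  invisible(x)
}

#' Write a drift report to CSV
#' @param report A `drift_report`.
#' @param trial_id Trial identifier for the `trial_id` column.
#' @param path Output path.
#' @export
write_drift_report_csv <- function(report, trial_id, path) {
  df <- data.frame(trial_id = trial_id,
                   ic_index = seq_len(nrow(report$ic_pairs)),
                   residual_s = report$ic_pairs$residual_s,
                   edits = report$ic_pairs$edits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
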