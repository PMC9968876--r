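#' Channel layout of the model input
#'
#' The 24 input channels are the 18 raw inertial channels (three sites
#' times ax, ay, az, gx, gy, gz) followed by six resultant magnitudes
#' (per-site acceleration magnitude and angular-velocity magnitude) --
#' the only reading of "raw channels plus their resultant magnitudes"
#' consistent with a 24-wide input.
#'
#' @return Character vector of 24 channel names.
#' @export
channel_layout <- function() {
  raw <- as.vector(vapply(IMU_SITES, function(s)
    paste(s, c("ax", "ay", "az", "gx", "gy", "gz"), sep = "."),
    character(6)))
  mags <- as.vector(vapply(IMU_SITES, function(s)
    paste(s, c("amag", "gmag"), sep = "."), character(2)))
  c(raw, mags)
}

#' Assemble the 24-channel input matrix
#'
#' @param imu_set Named list of three [imu_recording()]s (`left_foot`,
#'   `right_foot`, `sacrum`), already on a common 100 Hz grid of equal
#'   length.
#' @return T x 24 numeric matrix with [channel_layout()] column names.
#' @export
assemble_channels <- function(imu_set) {
  if (!all(IMU_SITES %in% names(imu_set)))
    stop("imu_set must contain left_foot, right_foot and sacrum",
         call. = FALSE)
  lens <- vapply(IMU_SITES, function(s) nrow(imu_set[[s]]$accel), integer(1))
  if (length(unique(lens)) != 1)
    stop("all three recordings must have equal length", call. = FALSE)
  raw <- do.call(cbind, lapply(IMU_SITES, function(s)
    cbind(imu_set[[s]]$accel, imu_set[[s]]$gyro)))
  mags <- do.call(cbind, lapply(IMU_SITES, function(s)
    cbind(sqrt(rowSums(imu_set[[s]]$accel^2)),
          sqrt(rowSums(imu_set[[s]]$gyro^2)))))
  m <- cbind(raw, mags)
  colnames(m) <- channel_layout()
  m
}

#' Summed bilateral force in body-weight units
#'
#' @param force A [force_recording()].
#' @param bw_threshold Values below this (BW) are zeroed (default 0.05,
#'   the 5% BW rule applied to measured force data).
#' @return Numeric vector, BW.
#' @export
sum_bilateral_force <- function(force, bw_threshold = 0.05) {
  y <- (force$force_left + force$force_right) / force$body_weight
  y[y < bw_threshold] <- 0
  y
}

#' One training window
#'
#' @param x 400 x 24 input matrix.
#' @param y Length-400 target force vector, BW.
#' @param trial_id Trial identifier.
#' @param start_index 1-based index of the window's first sample in the
#'   trial.
#' @param participant_id Participant the trial belongs to.
#' @return Object of class `window_pair`.
#' @export
window_pair <- function(x, y, trial_id, start_index, participant_id = NA) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (any(y < 0)) stop("target force must be non-negative", call. = FALSE)
  structure(list(x = x, y = as.numeric(y), trial_id = trial_id,
                 start_index = as.integer(start_index),
                 participant_id = participant_id),
            class = "window_pair")
}

#' Cut a trial into fixed-length windows
#'
#' Consecutive non-overlapping windows of `window_s * rate` samples
#' (400 at the defaults); a trailing remainder shorter than one window is
#' dropped. Windows are cut from the whole trial, so each one typically
#' contains several stance and swing phases.
#'
#' @param channels T x 24 input matrix.
#' @param force Length-T summed force, BW.
#' @param trial_id Trial identifier.
#' @param participant_id Participant identifier.
#' @param window_s Window length, s (default 4).
#' @param rate Sampling rate, Hz (default 100).
#' @return List of [window_pair()]s (empty, with a warning, if T is less
#'   than one window).
#' @export
make_windows <- function(channels, force, trial_id = "trial",
                         participant_id = NA, window_s = 4, rate = 100) {
  stopifnot(nrow(channels) == length(force))
  len <- as.integer(round(window_s * rate))
  n <- nrow(channels) %/% len
  if (n == 0) {
    warning("trial shorter than one window: no windows produced")
    return(list())
  }
  lapply(seq_len(n), function(i) {
    s <- (i - 1L) * len + 1L
    window_pair(channels[s:(s + len - 1L), , drop = FALSE],
                force[s:(s + len - 1L)], trial_id, s, participant_id)
  })
}

#' Reassemble window-level estimates into a trial waveform
#'
#' @param window_outputs List of numeric vectors ordered by start index.
#' @param start_indices 1-based start index of each window.
#' @param trial_length Length of the full trial, samples.
#' @return Numeric vector of length `trial_length`; samples past the last
#'   window (the dropped remainder) are zero-filled and flagged via the
#'   `"tail_filled"` attribute.
#' @export
concatenate_estimates <- function(window_outputs, start_indices,
                                  trial_length) {
  stopifnot(length(window_outputs) == length(start_indices))
  if (length(window_outputs) == 0)
    return(structure(numeric(trial_length), tail_filled = trial_length))
  lens <- lengths(window_outputs)
  if (is.unsorted(start_indices, strictly = TRUE))
    stop("windows out of order", call. = FALSE)
  ends <- start_indices + lens - 1L
  if (any(start_indices[-1] != ends[-length(ends)] + 1L) ||
      start_indices[1] != 1L)
    stop("windows must tile the trial without gaps or overlap",
         call. = FALSE)
  covered <- ends[length(ends)]
  if (covered > trial_length)
    stop("windows extend past trial_length", call. = FALSE)
  out <- numeric(trial_length)
  out[seq_len(covered)] <- unlist(window_outputs)
  structure(out, tail_filled = trial_length - covered)
}
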