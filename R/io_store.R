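#' @useDynLib imugrf, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

GRAVITY <- 9.81  # m s^-2, used for body-weight normalization

IMU_COLS <- c("time_s", "ax_ms2", "ay_ms2", "az_ms2",
              "gx_rads", "gy_rads", "gz_rads")
FORCE_COLS <- c("time_s", "force_left_n", "force_right_n")
IMU_SITES <- c("left_foot", "right_foot", "sacrum")

#' Construct an IMU recording
#'
#' One sensor's six-channel inertial stream: tri-axial linear acceleration
#' (m s^-2, gravity-aligned frame) and tri-axial angular velocity
#' (rad s^-1), sampled nominally at 200 Hz.
#'
#' @param site Mounting site: `"left_foot"`, `"right_foot"` or `"sacrum"`.
#' @param time Seconds from session start, strictly increasing.
#' @param accel T x 3 matrix of accelerations, m s^-2.
#' @param gyro T x 3 matrix of angular velocities, rad s^-1.
#' @param rate Sampling rate, Hz.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(site, time, accel, gyro, rate) {
  site <- match.arg(site, IMU_SITES)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (ncol(accel) != 3 || ncol(gyro) != 3)
    stop("accel and gyro must each have 3 columns", call. = FALSE)
  if (nrow(accel) != length(time) || nrow(gyro) != length(time))
    stop("time, accel and gyro must have matching length", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (!all(is.finite(accel)) || !all(is.finite(gyro)))
    stop("inertial channels must be finite", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  structure(list(site = site, time = as.numeric(time),
                 accel = unname(accel), gyro = unname(gyro),
                 rate = rate),
            class = "imu_recording")
}

#' Construct a force recording
#'
#' Bilateral insole normal forces in newtons with the participant's body
#' weight, so downstream stages can normalize to BW units.
#'
#' @param time Seconds, strictly increasing.
#' @param force_left,force_right Normal force per insole, N. Values in
#'   (-1, 0) N are treated as sensor baseline noise and clamped to 0;
#'   anything at or below -1 N is a data error.
#' @param rate Sampling rate, Hz.
#' @param body_weight Body weight, N (mass x 9.81).
#' @return An object of class `force_recording`.
#' @export
force_recording <- function(time, force_left, force_right, rate, body_weight) {
  if (length(force_left) != length(time) || length(force_right) != length(time))
    stop("force channels must match time length", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(force_left <= -1) || any(force_right <= -1))
    stop("force values below -1 N found; data error", call. = FALSE)
  if (body_weight <= 0) stop("body_weight must be positive", call. = FALSE)
  structure(list(time = as.numeric(time),
                 force_left = pmax(as.numeric(force_left), 0),
                 force_right = pmax(as.numeric(force_right), 0),
                 rate = rate, body_weight = body_weight),
            class = "force_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> site=%s, %d samples @ %g Hz, %.1f s\n",
              x$site, length(x$time), x$rate,
              diff(range(x$time))))
  invisible(x)
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> %d samples @ %g Hz, BW=%.1f N\n",
              length(x$time), x$rate, x$body_weight))
  invisible(x)
}

infer_rate <- function(time) {
  if (length(time) < 2) stop("need at least 2 samples to infer rate",
                             call. = FALSE)
  1 / stats::median(diff(time))
}

#' Read an IMU CSV file
#'
#' Expects columns `time_s,ax_ms2,ay_ms2,az_ms2,gx_rads,gy_rads,gz_rads`.
#' The site is parsed from the filename suffix (`_lfoot`, `_rfoot`,
#' `_sacrum`) unless given explicitly.
#'
#' @param path CSV file path.
#' @param site Optional site override.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, site = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), IMU_COLS))
    stop("malformed IMU CSV header in ", path,
         " (expected ", paste(IMU_COLS, collapse = ","), ")", call. = FALSE)
  if (is.null(site)) {
    base <- basename(path)
    site <- if (grepl("_lfoot", base)) "left_foot"
            else if (grepl("_rfoot", base)) "right_foot"
            else if (grepl("_sacrum", base)) "sacrum"
            else stop("cannot infer site from filename: ", base, call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time in ", path, call. = FALSE)
  imu_recording(site, df$time_s,
                as.matrix(df[, 2:4]), as.matrix(df[, 5:7]),
                rate = infer_rate(df$time_s))
}

#' Write an IMU CSV file
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  write_numeric_csv(cbind(rec$time, rec$accel, rec$gyro), IMU_COLS, path)
}

# shortest round-trip-exact decimal representation (%.17g would also do,
# but R's formatting already guarantees read-back bit equality at 17 digits)
write_numeric_csv <- function(m, cols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  rows <- do.call(paste, c(lapply(seq_len(ncol(m)), function(j)
    formatC(m[, j], digits = 17, format = "g")), sep = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Read an insole force CSV file
#'
#' Expects columns `time_s,force_left_n,force_right_n`. Small negative
#' readings (> -1 N) are clamped to zero.
#'
#' @param path CSV file path.
#' @param mass_kg Participant mass, kg; body weight is `mass_kg * 9.81` N.
#' @return A [force_recording()].
#' @export
read_force_csv <- function(path, mass_kg) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (mass_kg <= 0) stop("mass_kg must be positive", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), FORCE_COLS))
    stop("malformed force CSV header in ", path, call. = FALSE)
  force_recording(df$time_s, df$force_left_n, df$force_right_n,
                  rate = infer_rate(df$time_s),
                  body_weight = mass_kg * GRAVITY)
}

#' Write an insole force CSV file
#' @param rec A [force_recording()].
#' @param path Output path.
#' @export
write_force_csv <- function(rec, path) {
  stopifnot(inherits(rec, "force_recording"))
  write_numeric_csv(cbind(rec$time, rec$force_left, rec$force_right),
                    FORCE_COLS, path)
}

#' Write measured and estimated GRF waveforms for one trial
#'
#' @param trial_id Trial identifier.
#' @param time Time stamps, seconds.
#' @param measured_bw,estimated_bw Equal-length waveforms in BW.
#' @param path Output path.
#' @export
write_estimates_csv <- function(trial_id, time, measured_bw, estimated_bw,
                                path) {
  n <- length(time)
  if (length(measured_bw) != n || length(estimated_bw) != n)
    stop("time, measured and estimated vectors must have equal length",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,grf_bw_measured,grf_bw_estimated", con)
  if (n > 0)
    writeLines(sprintf("%.6f,%.6f,%.6f", time, measured_bw, estimated_bw),
               con)
  invisible(path)
}

#' Read back an estimates CSV
#' @param path File written by [write_estimates_csv()].
#' @return data.frame with `time_s`, `grf_bw_measured`, `grf_bw_estimated`.
#' @export
read_estimates_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a trial manifest
#'
#' The manifest is a human-editable key-value text file, one document per
#' participant, listing mass and the per-trial file paths (three IMU CSVs
#' and one insole CSV per trial).
#'
#' @param manifest A `trial_manifest` as returned by [read_manifest()] or
#'   built by the simulator.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("participant_id: ", manifest$participant_id),
               paste0("mass_kg: ", format(manifest$mass_kg, digits = 10)),
               paste0("seed: ", manifest$seed)), con)
  for (tr in manifest$trials) {
    writeLines(c("trial:",
                 paste0("  trial_id: ", tr$trial_id),
                 paste0("  pace_label: ", tr$pace_label),
                 paste0("  target_velocity: ",
                        format(tr$target_velocity, digits = 10)),
                 paste0("  imu_lfoot: ", tr$imu_paths[["left_foot"]]),
                 paste0("  imu_rfoot: ", tr$imu_paths[["right_foot"]]),
                 paste0("  imu_sacrum: ", tr$imu_paths[["sacrum"]]),
                 paste0("  force: ", tr$force_path)), con)
  }
  invisible(path)
}

#' Read a trial manifest
#' @param path Manifest file path.
#' @return A `trial_manifest`: list with `participant_id`, `mass_kg`,
#'   `seed` and `trials` (each with `trial_id`, `pace_label`,
#'   `target_velocity`, named `imu_paths`, `force_path`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- function(l) {
    m <- regmatches(l, regexec("^\\s*([a-z_]+):\\s*(.*)$", l))[[1]]
    if (length(m) < 3) stop("malformed manifest line: ", l, call. = FALSE)
    m[2:3]
  }
  out <- list(trials = list())
  cur <- NULL
  flush_cur <- function(out, cur) {
    if (!is.null(cur)) out$trials[[length(out$trials) + 1]] <- cur
    out
  }
  for (l in lines) {
    if (!nzchar(trimws(l))) next
    p <- kv(l)
    key <- p[1]; val <- trimws(p[2])
    if (key == "trial") {
      out <- flush_cur(out, cur)
      cur <- list(imu_paths = c(left_foot = NA, right_foot = NA, sacrum = NA))
    } else if (is.null(cur)) {
      out[[key]] <- if (key %in% c("mass_kg", "seed")) as.numeric(val) else val
    } else {
      switch(key,
        trial_id = { cur$trial_id <- val },
        pace_label = { cur$pace_label <- val },
        target_velocity = { cur$target_velocity <- as.numeric(val) },
        imu_lfoot = { cur$imu_paths[["left_foot"]] <- val },
        imu_rfoot = { cur$imu_paths[["right_foot"]] <- val },
        imu_sacrum = { cur$imu_paths[["sacrum"]] <- val },
        force = { cur$force_path <- val },
        stop("unknown manifest key: ", key, call. = FALSE))
    }
  }
  out <- flush_cur(out, cur)
  for (tr in out$trials) {
    if (anyNA(tr$imu_paths) || is.null(tr$force_path))
      stop("trial ", tr$trial_id,
           " must reference three IMU files and one force file",
           call. = FALSE)
    v <- tr$target_velocity
    if (!is.na(v) && (v < 2.0 || v > 6.0))
      warning("target velocity ", v, " m/s outside the modeled range [2, 6]")
  }
  class(out) <- "trial_manifest"
  out
}

#' Load all recordings referenced by a manifest
#'
#' @param manifest A `trial_manifest`.
#' @param base_dir Directory that relative paths in the manifest resolve
#'   against (defaults to the working directory).
#' @return Named list (by trial id) of lists with `imu` (three
#'   [imu_recording()]s named by site), `force`, `target_velocity`,
#'   `pace_label`.
#' @export
load_manifest_trials <- function(manifest, base_dir = ".") {
  res <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  out <- lapply(manifest$trials, function(tr) {
    imus <- lapply(IMU_SITES, function(s) read_imu_csv(res(tr$imu_paths[[s]]),
                                                       site = s))
    names(imus) <- IMU_SITES
    list(trial_id = tr$trial_id,
         imu = imus,
         force = read_force_csv(res(tr$force_path), manifest$mass_kg),
         target_velocity = tr$target_velocity,
         pace_label = tr$pace_label)
  })
  names(out) <- vapply(manifest$trials, `[[`, "", "trial_id")
  out
}
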