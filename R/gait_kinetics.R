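#' Post-process an estimated GRF waveform
#'
#' Applies the same cleaning chain used for measured insole data to a
#' concatenated model estimate: a 2nd-order 20 Hz zero-lag low-pass,
#' zeroing of values below 5% BW, and removal of supra-threshold contacts
#' shorter than 0.050 s, which are too brief to be running foot contacts
#' and are treated as estimation noise.
#'
#' @param y_hat Trial-length estimated waveform, BW.
#' @param rate Sampling rate, Hz (default 100).
#' @param bw_threshold Force threshold, BW (default 0.05).
#' @param min_contact_s Minimum credible contact duration, s (default 0.050).
#' @param filter Logical; apply the 20 Hz low-pass first (default TRUE).
#' @return Cleaned waveform, BW.
#' @export
postprocess_estimate <- function(y_hat, rate = 100, bw_threshold = 0.05,
                                 min_contact_s = 0.050, filter = TRUE) {
  y <- y_hat
  if (filter && length(y) > 3 * 2) {
    y <- lowpass_zero_lag(y, force_filter_spec(), rate)
  }
  y[y < bw_threshold] <- 0
  runs <- contiguous_runs(y > 0)
  if (nrow(runs) > 0) {
    min_len <- ceiling(min_contact_s * rate)
    for (i in seq_len(nrow(runs))) {
      len <- runs$end[i] - runs$start[i] + 1L
      if (len < min_len) y[runs$start[i]:runs$end[i]] <- 0
    }
  }
  y
}

# start/end indices (inclusive) of runs of TRUE
contiguous_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect stance phases from a GRF waveform
#'
#' Initial contact (IC) is the first sample with force above 5% BW in a
#' contiguous supra-threshold run and toe off (TO) the last such sample;
#' contact time is their difference. Indices are 1-based; times are
#' `(idx - 1) / rate` on the waveform's own grid.
#'
#' @param force_bw Cleaned summed GRF waveform, BW.
#' @param rate Sampling rate, Hz.
#' @param bw_threshold Event threshold, BW (default 0.05; strict `>`).
#' @param drop_edges Drop stances touching the first or last sample of the
#'   waveform (truncated by recording boundaries). Default TRUE.
#' @return data.frame with columns `ic_idx`, `to_idx`, `ic_s`, `to_s`,
#'   `contact_time_s`; zero rows (with a warning) if no stance is found.
#' @export
detect_stances <- function(force_bw, rate, bw_threshold = 0.05,
                           drop_edges = TRUE) {
  runs <- contiguous_runs(force_bw > bw_threshold)
  if (drop_edges && nrow(runs) > 0) {
    keep <- runs$start > 1L & runs$end < length(force_bw)
    runs <- runs[keep, , drop = FALSE]
  }
  if (nrow(runs) == 0) {
    warning("no stance phases detected")
    return(data.frame(ic_idx = integer(), to_idx = integer(),
                      ic_s = numeric(), to_s = numeric(),
                      contact_time_s = numeric()))
  }
  data.frame(ic_idx = runs$start, to_idx = runs$end,
             ic_s = (runs$start - 1) / rate,
             to_s = (runs$end - 1) / rate,
             contact_time_s = (runs$end - runs$start) / rate)
}

#' Contact time of a stance
#' @param ev One-row stance event (from [detect_stances()]).
#' @return Contact time, seconds.
#' @export
contact_time <- function(ev) ev$to_s - ev$ic_s

# linear interpolation of the waveform at a fractional sample time
interp_force <- function(force_bw, rate, t) {
  stats::approx(x = (seq_along(force_bw) - 1) / rate, y = force_bw,
                xout = t, rule = 2)$y
}

#' Locate the impact peak of a stance
#'
#' The impact peak is the transient local force maximum early in stance
#' caused by the foot-ground collision. It is identified as the first
#' local maximum within the first 35% of stance whose prominence is at
#' least `min_prominence` BW; `NA` when no such peak exists (e.g. a
#' smooth mid-foot-strike-like rise).
#'
#' @param force_bw Waveform, BW.
#' @param ev One-row stance event.
#' @param rate Sampling rate, Hz.
#' @param min_prominence Minimum peak prominence, BW (default 0.05).
#' @return Peak time in seconds, or `NA` if absent.
#' @export
find_impact_peak <- function(force_bw, ev, rate, min_prominence = 0.05) {
  span <- force_bw[ev$ic_idx:ev$to_idx]
  n <- length(span)
  lim <- max(3L, floor(0.35 * n))
  for (i in 2:(lim - 1)) {
    if (span[i] > span[i - 1] && span[i] >= span[i + 1]) {
      # prominence: drop to the lowest point before re-exceeding the peak
      left_min <- min(span[1:i])
      j <- i + 1L
      while (j <= n && span[j] < span[i]) j <- j + 1L
      right_min <- if (j > i + 1L) min(span[(i + 1L):(j - 1L)]) else span[i]
      prom <- span[i] - max(left_min, right_min)
      if (prom >= min_prominence)
        return(ev$ic_s + (i - 1) / rate)
    }
  }
  NA_real_
}

#' Average vertical loading rate of a stance
#'
#' Default strategy `"impact_peak"`: average slope over the middle 60% of
#' the interval from IC to the impact peak, i.e. the secant slope between
#' 20% and 80% of that interval (on a uniform grid the mean of pointwise
#' slopes telescopes to exactly this secant). When no impact peak exists,
#' or with `strategy = "fixed_window"`, the slope is taken between 10%
#' and 40% of contact time instead.
#'
#' @param force_bw Waveform, BW.
#' @param ev One-row stance event.
#' @param rate Sampling rate, Hz.
#' @param strategy `"impact_peak"` (default, with fixed-window fallback)
#'   or `"fixed_window"`.
#' @return Loading rate, BW s^-1.
#' @export
average_loading_rate <- function(force_bw, ev, rate,
                                 strategy = c("impact_peak", "fixed_window")) {
  strategy <- match.arg(strategy)
  tp <- if (strategy == "impact_peak") find_impact_peak(force_bw, ev, rate)
        else NA_real_
  if (!is.na(tp)) {
    t1 <- ev$ic_s + 0.2 * (tp - ev$ic_s)
    t2 <- ev$ic_s + 0.8 * (tp - ev$ic_s)
  } else {
    tc <- ev$to_s - ev$ic_s
    t1 <- ev$ic_s + 0.1 * tc
    t2 <- ev$ic_s + 0.4 * tc
  }
  if ((t2 - t1) * rate < 1)
    stop("loading-rate interval shorter than one sample; degenerate stance",
         call. = FALSE)
  (interp_force(force_bw, rate, t2) - interp_force(force_bw, rate, t1)) /
    (t2 - t1)
}

#' Kinetic variables of one stance
#'
#' Computes the stance average force (mean over the IC..TO span, BW), the
#' impulse (trapezoidal integral, BW s), the peak force (BW), the contact
#' time (s) and the average loading rate (BW s^-1).
#'
#' @inheritParams average_loading_rate
#' @return One-row data.frame: `contact_time_s`, `stance_average_bw`,
#'   `impulse_bw_s`, `peak_bw`, `loading_rate_bw_s`.
#' @export
stance_kinetics <- function(force_bw, ev, rate,
                            strategy = c("impact_peak", "fixed_window")) {
  strategy <- match.arg(strategy)
  if (ev$to_idx - ev$ic_idx + 1 < 3)
    stop("degenerate stance: fewer than 3 samples", call. = FALSE)
  span <- force_bw[ev$ic_idx:ev$to_idx]
  n <- length(span)
  data.frame(
    contact_time_s = ev$to_s - ev$ic_s,
    stance_average_bw = mean(span),
    impulse_bw_s = sum((span[-1] + span[-n]) / 2) / rate,
    peak_bw = max(span),
    loading_rate_bw_s = average_loading_rate(force_bw, ev, rate, strategy))
}

#' Kinetics for every stance in a trial
#'
#' @param force_bw Cleaned waveform, BW.
#' @param rate Sampling rate, Hz.
#' @param strategy Loading-rate strategy, see [average_loading_rate()].
#' @return data.frame: one row per stance with event columns from
#'   [detect_stances()] plus the [stance_kinetics()] columns.
#' @export
trial_kinetics <- function(force_bw, rate,
                           strategy = c("impact_peak", "fixed_window")) {
  strategy <- match.arg(strategy)
  ev <- detect_stances(force_bw, rate)
  if (nrow(ev) == 0) return(cbind(ev, data.frame(
    contact_time_s2 = numeric(0))))
  ks <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    stance_kinetics(force_bw, ev[i, ], rate, strategy)))
  cbind(ev[c("ic_idx", "to_idx", "ic_s", "to_s")], ks)
}
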