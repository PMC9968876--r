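#' Whole-waveform RMSE
#'
#' Root mean squared difference over every sample of the trial, swing
#' phases included.
#'
#' @param measured,estimated Equal-length waveforms, BW.
#' @return RMSE, BW.
#' @export
waveform_rmse <- function(measured, estimated) {
  if (length(measured) != length(estimated))
    stop("waveforms must have equal length", call. = FALSE)
  sqrt(mean((measured - estimated)^2))
}

#' Stance-phase RMSE
#'
#' RMSE restricted to the stance spans of the measured waveform (the
#' measurement standard defines the evaluation region): the RMSE is
#' computed per stance, then averaged over stances.
#'
#' @param measured,estimated Equal-length waveforms, BW.
#' @param stances_measured Stances from [detect_stances()] on `measured`.
#' @return Mean per-stance RMSE, BW; `NA` when there are no stances.
#' @export
stance_rmse <- function(measured, estimated, stances_measured) {
  if (length(measured) != length(estimated))
    stop("waveforms must have equal length", call. = FALSE)
  if (nrow(stances_measured) == 0) return(NA_real_)
  per <- vapply(seq_len(nrow(stances_measured)), function(i) {
    idx <- stances_measured$ic_idx[i]:stances_measured$to_idx[i]
    sqrt(mean((measured[idx] - estimated[idx])^2))
  }, numeric(1))
  mean(per)
}

#' Gait-event differences between measured and estimated waveforms
#'
#' Events are paired by nearest IC time within `pairing_tol`; differences
#' are signed measured minus estimated, so a positive IC difference means
#' the estimate placed initial contact early.
#'
#' @param measured_events,estimated_events Stance tables from
#'   [detect_stances()].
#' @param pairing_tol Maximum pairing distance, s (default 0.1).
#' @return List: `ic_diffs`, `to_diffs` (per matched pair, s), `pairs`
#'   (index pairs), `unpaired_measured`, `unpaired_estimated` (counts).
#' @export
event_differences <- function(measured_events, estimated_events,
                              pairing_tol = 0.1) {
  nm <- nrow(measured_events); ne <- nrow(estimated_events)
  used <- logical(ne)
  mi <- integer(0); ei <- integer(0)
  for (i in seq_len(nm)) {
    if (ne == 0) break
    d <- abs(estimated_events$ic_s - measured_events$ic_s[i])
    d[used] <- Inf
    k <- which.min(d)
    if (d[k] <= pairing_tol) {
      used[k] <- TRUE
      mi <- c(mi, i); ei <- c(ei, k)
    }
  }
  list(ic_diffs = measured_events$ic_s[mi] - estimated_events$ic_s[ei],
       to_diffs = measured_events$to_s[mi] - estimated_events$to_s[ei],
       pairs = data.frame(measured = mi, estimated = ei),
       unpaired_measured = nm - length(mi),
       unpaired_estimated = ne - length(ei))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are estimated minus measured; the bias is their mean and
#' the 95% limits of agreement are bias +/- 1.96 times their sample
#' standard deviation (n-1 denominator).
#'
#' @param estimated_values,measured_values Paired trial-level values.
#' @return List: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(estimated_values, measured_values) {
  n <- length(estimated_values)
  if (length(measured_values) != n)
    stop("paired vectors must have equal length", call. = FALSE)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  d <- estimated_values - measured_values
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = n)
}

#' Squared Pearson correlation with a strength label
#'
#' Bands: strong `r2 >= 0.8`, moderate `[0.5, 0.8)`, weak `[0.3, 0.5)`,
#' negligible below 0.3.
#'
#' @param estimated_values,measured_values Paired values (n >= 3).
#' @return List: `r2`, `label` (`"undefined"` with `r2 = NA` when either
#'   vector has zero variance).
#' @export
correlation_r2 <- function(estimated_values, measured_values) {
  n <- length(estimated_values)
  if (length(measured_values) != n || n < 3)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(estimated_values) < 1e-12 ||
      stats::sd(measured_values) < 1e-12)
    return(list(r2 = NA_real_, label = "undefined"))
  r2 <- stats::cor(estimated_values, measured_values)^2
  list(r2 = r2, label = r2_label(r2))
}

#' @rdname correlation_r2
#' @param r2 A squared correlation in [0, 1].
#' @export
r2_label <- function(r2) {
  if (r2 >= 0.8) "strong"
  else if (r2 >= 0.5) "moderate"
  else if (r2 >= 0.3) "weak"
  else "negligible"
}

#' Ordinary least squares agreement regression
#'
#' Regresses estimated on measured values and reports slope and intercept
#' with t-based 95% confidence intervals.
#'
#' @param estimated_values,measured_values Paired trial-level values.
#' @return List: `slope`, `intercept`, `slope_ci`, `intercept_ci` (each
#'   CI a length-2 vector), `r2`.
#' @export
agreement_regression <- function(estimated_values, measured_values) {
  fit <- stats::lm(estimated_values ~ measured_values)
  ci <- stats::confint(fit, level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
       r2 = summary(fit)$r.squared)
}

KINETIC_VARS <- c("contact_time_s", "stance_average_bw", "impulse_bw_s",
                  "peak_bw", "loading_rate_bw_s")

#' Per-trial agreement between measured and estimated waveforms
#'
#' Pairs stances between the two waveforms, computes kinetics for each
#' paired stance on both, and summarizes the trial: stance and waveform
#' RMSE, mean signed IC/TO differences, per-variable RMSE across paired
#' stances, and trial-mean measured and estimated values of each kinetic
#' variable (the values that enter regression and Bland-Altman analyses).
#'
#' @param measured_bw,estimated_bw Cleaned equal-length waveforms, BW.
#' @param rate Sampling rate, Hz.
#' @param trial_id,velocity Trial metadata.
#' @param strategy Loading-rate strategy, see [average_loading_rate()].
#' @return One-row data.frame (class `trial_agreement` rows are plain
#'   data).
#' @export
trial_agreement <- function(measured_bw, estimated_bw, rate,
                            trial_id = "trial", velocity = NA,
                            strategy = "impact_peak") {
  ev_m <- detect_stances(measured_bw, rate)
  ev_e <- detect_stances(estimated_bw, rate)
  diffs <- event_differences(ev_m, ev_e)
  row <- data.frame(trial_id = trial_id, velocity = velocity,
                    n_stances = nrow(diffs$pairs),
                    stance_rmse_bw = stance_rmse(measured_bw, estimated_bw,
                                                 ev_m),
                    waveform_rmse_bw = waveform_rmse(measured_bw,
                                                     estimated_bw),
                    ic_diff_s = mean(diffs$ic_diffs),
                    to_diff_s = mean(diffs$to_diffs))
  km <- ke <- matrix(NA_real_, nrow(diffs$pairs), length(KINETIC_VARS),
                     dimnames = list(NULL, KINETIC_VARS))
  for (j in seq_len(nrow(diffs$pairs))) {
    sm <- stance_kinetics(measured_bw, ev_m[diffs$pairs$measured[j], ],
                          rate, strategy)
    se <- stance_kinetics(estimated_bw, ev_e[diffs$pairs$estimated[j], ],
                          rate, strategy)
    km[j, ] <- as.numeric(sm[KINETIC_VARS])
    ke[j, ] <- as.numeric(se[KINETIC_VARS])
  }
  for (v in KINETIC_VARS) {
    row[[paste0(v, "_rmse")]] <- sqrt(mean((km[, v] - ke[, v])^2))
    row[[paste0(v, "_measured")]] <- mean(km[, v])
    row[[paste0(v, "_estimated")]] <- mean(ke[, v])
  }
  row
}

#' Per-velocity summary table
#'
#' Aggregates trial agreements by target velocity: mean and SD of stance
#' RMSE, waveform RMSE, IC/TO differences and each kinetic variable's
#' RMSE. Velocities with a single trial report an SD of 0, consistent
#' with presenting a lone trial as its own mean.
#'
#' @param trial_agreements data.frame of [trial_agreement()] rows.
#' @return data.frame, one row per distinct velocity (empty input gives
#'   an empty table).
#' @export
per_velocity_summary <- function(trial_agreements) {
  if (nrow(trial_agreements) == 0) return(data.frame())
  cols <- c("stance_rmse_bw", "waveform_rmse_bw", "ic_diff_s", "to_diff_s",
            paste0(KINETIC_VARS, "_rmse"))
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  vs <- sort(unique(trial_agreements$velocity))
  out <- lapply(vs, function(v) {
    g <- trial_agreements[trial_agreements$velocity == v, , drop = FALSE]
    row <- data.frame(velocity = v, n_trials = nrow(g))
    for (cl in cols) {
      row[[paste0(cl, "_mean")]] <- mean(g[[cl]])
      row[[paste0(cl, "_sd")]] <- sd0(g[[cl]])
    }
    row
  })
  do.call(rbind, out)
}

#' Variable-level agreement table
#'
#' For each kinetic variable, Bland-Altman bias and limits of agreement
#' plus squared correlation across trial-level values.
#'
#' @param trial_agreements data.frame of [trial_agreement()] rows
#'   (n >= 3).
#' @return data.frame: `variable,bias,loa_low,loa_high,r2,label,n`.
#' @export
variable_agreement <- function(trial_agreements) {
  out <- lapply(c("contact_time_s", KINETIC_VARS[-1]), function(v) {
    est <- trial_agreements[[paste0(v, "_estimated")]]
    mea <- trial_agreements[[paste0(v, "_measured")]]
    ok <- is.finite(est) & is.finite(mea)
    ba <- bland_altman(est[ok], mea[ok])
    r2 <- correlation_r2(est[ok], mea[ok])
    data.frame(variable = v, bias = ba$bias, loa_low = ba$loa_low,
               loa_high = ba$loa_high, r2 = r2$r2, label = r2$label,
               n = ba$n)
  })
  do.call(rbind, out)
}
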