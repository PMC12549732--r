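#' Gait event-detection thresholds
#'
#' Configuration of the shank-gyro event detector: a zero-phase Butterworth
#' band-pass, a mid-swing peak threshold, a minimum stride gap, and search
#' windows (relative to each mid-swing) for the heel-strike and toe-off
#' minima. All values are configuration; the defaults suit toddler gait
#' sampled at 100 Hz.
#'
#' @param band_hz Band-pass corner frequencies (Hz).
#' @param filter_order Butterworth section order (applied forward-backward,
#'   so the effective attenuation is doubled).
#' @param ms_threshold Mid-swing peak threshold (deg/s).
#' @param min_stride_gap_s Minimum separation between mid-swing peaks (s).
#' @param hs_window_s Heel-strike search window after mid-swing, `(from, to)` s.
#' @param to_window_s Toe-off search window before mid-swing, `(from, to)` s
#'   (i.e. the window `[ms - from, ms - to]`).
#' @param axis Sagittal gyro channel: `"auto"` picks the channel with the
#'   largest variance; otherwise one of `"x","y","z"`.
#' @return Object of class `event_thresholds`.
#' @export
event_thresholds <- function(band_hz = c(0.5, 10), filter_order = 2L,
                             ms_threshold = 50, min_stride_gap_s = 0.4,
                             hs_window_s = c(0.05, 0.4),
                             to_window_s = c(0.4, 0.05),
                             axis = "auto") {
  structure(list(band_hz = band_hz, filter_order = as.integer(filter_order),
                 ms_threshold = ms_threshold,
                 min_stride_gap_s = min_stride_gap_s,
                 hs_window_s = hs_window_s, to_window_s = to_window_s,
                 axis = axis), class = "event_thresholds")
}

#' Detect gait events from shank angular velocity
#'
#' Band-pass filters the sagittal shank-gyro channel (zero phase), locates
#' mid-swing peaks (local maxima above threshold separated by at least the
#' minimum stride gap), then finds the heel strike as the deepest minimum
#' in a window after each mid-swing and the toe-off as the deepest minimum
#' in a window before it. The signal is sign-oriented so that the dominant
#' swing peak is positive.
#'
#' @param gyro Numeric vector (sagittal channel, deg/s) or an n x 3 matrix
#'   of gyro channels from which the sagittal axis is selected.
#' @param fs Sampling rate (Hz).
#' @param thresholds An [event_thresholds()] object.
#' @param leg Label stored on the result (`"left"`/`"right"`).
#' @return Object of class `stride_series`: `leg`, `heel_strikes`,
#'   `toe_offs`, `mid_swings` (times in s, strictly increasing).
#' @export
detect_gait_events <- function(gyro, fs, thresholds = event_thresholds(),
                               leg = "left") {
  if (fs <= 0) abort_gw("fs must be positive", "gaitwin_validation_error")
  if (is.matrix(gyro)) {
    ax <- thresholds$axis
    col <- if (identical(ax, "auto")) which.max(apply(gyro, 2, var)) else ax
    gyro <- gyro[, col]
  }
  n <- length(gyro)
  if (n < 2 * fs)
    abort_gw("need at least 2 s of data", "gaitwin_validation_error")

  ny <- fs / 2
  bf <- signal::butter(thresholds$filter_order,
                       pmin(thresholds$band_hz / ny, 0.99), type = "pass")
  x <- signal::filtfilt(bf, gyro)
  if (abs(min(x)) > abs(max(x))) x <- -x

  ms_idx <- find_ms_peaks(x, fs, thresholds)
  if (length(ms_idx) == 0L)
    abort_gw("no mid-swing peak above threshold",
             "gaitwin_no_strides_error")

  hs_off <- round(thresholds$hs_window_s * fs)
  to_off <- round(thresholds$to_window_s * fs)
  hs_idx <- vapply(ms_idx, function(i) {
    win <- seq(i + hs_off[1], min(n, i + hs_off[2]))
    win <- win[win <= n]
    if (length(win) < 2) return(NA_integer_)
    deepest_minimum(x, win)
  }, integer(1))
  to_idx <- vapply(ms_idx, function(i) {
    win <- seq(max(1, i - to_off[1]), i - to_off[2])
    win <- win[win >= 1]
    if (length(win) < 2) return(NA_integer_)
    deepest_minimum(x, win)
  }, integer(1))

  keep <- !is.na(hs_idx) & !is.na(to_idx)
  hs_idx <- hs_idx[keep]; to_idx <- to_idx[keep]; ms_idx <- ms_idx[keep]
  if (length(hs_idx) < 3L)
    abort_gw(sprintf("only %d strides detected (need >= 3)", length(hs_idx)),
             "gaitwin_insufficient_strides_error")

  structure(list(leg = leg,
                 heel_strikes = (hs_idx - 1) / fs,
                 toe_offs = (to_idx - 1) / fs,
                 mid_swings = (ms_idx - 1) / fs),
            class = "stride_series")
}

# Local maxima above threshold, greedily thinned to respect the minimum
# stride gap (taller peaks win).
find_ms_peaks <- function(x, fs, th) {
  n <- length(x)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] >= th$ms_threshold]
  if (length(cand) == 0L) return(integer())
  gap <- round(th$min_stride_gap_s * fs)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer()
  for (c0 in cand)
    if (!length(kept) || all(abs(kept - c0) >= gap)) kept <- c(kept, c0)
  sort(kept)
}

# Deepest local minimum within a window; falls back to the window argmin
# when no interior local minimum exists.
deepest_minimum <- function(x, win) {
  interior <- win[win > 1 & win < length(x)]
  lm <- interior[x[interior] <= x[interior - 1] & x[interior] < x[interior + 1]]
  if (length(lm)) lm[which.min(x[lm])] else win[which.min(x[win])]
}

#' Temporal gait parameters from left/right stride events
#'
#' Computes the per-stride temporal battery: stride time (successive
#' ipsilateral heel strikes), step time (ipsilateral to contralateral heel
#' strike), stance time and double-support time as percentages of the
#' stride, and dimensionless stride/step times normalised by the pendulum
#' time `sqrt(body_length_m / 9.81)`.
#'
#' @param left,right `stride_series` for each leg.
#' @param body_length_m Body length at assessment (m); if missing the
#'   dimensionless times are `NA` with a warning.
#' @return Object of class `temporal_params` with per-stride vectors
#'   (`strideT_values`, `stepT_values`, `stanceT_values`, `DS_values`) and
#'   scalar summaries (`strideT`, `nstrideT`, `stepT`, `nstepT`, `stanceT`,
#'   `DS`).
#' @export
temporal_parameters <- function(left, right, body_length_m = NULL) {
  stopifnot(inherits(left, "stride_series"), inherits(right, "stride_series"))
  if (length(left$heel_strikes) < 4L || length(right$heel_strikes) < 4L)
    abort_gw("need >= 3 strides per leg", "gaitwin_insufficient_strides_error")

  stride_l <- diff(left$heel_strikes)
  stride_r <- diff(right$heel_strikes)

  # plausible interleaving: each left stride contains exactly one right HS
  per_stride <- function(ipsi_hs, contra_hs) {
    vapply(seq_len(length(ipsi_hs) - 1L), function(k) {
      inside <- contra_hs[contra_hs > ipsi_hs[k] & contra_hs < ipsi_hs[k + 1]]
      if (length(inside) == 1L) inside else NA_real_
    }, numeric(1))
  }
  r_in_l <- per_stride(left$heel_strikes, right$heel_strikes)
  l_in_r <- per_stride(right$heel_strikes, left$heel_strikes)
  if (mean(is.na(r_in_l)) > 0.5 || mean(is.na(l_in_r)) > 0.5)
    abort_gw("left/right events do not interleave plausibly",
             "gaitwin_event_sequence_error")

  step_l <- r_in_l - left$heel_strikes[-length(left$heel_strikes)]
  step_r <- l_in_r - right$heel_strikes[-length(right$heel_strikes)]
  step_all <- c(step_l[!is.na(step_l)], step_r[!is.na(step_r)])

  stance_pc <- function(ss) {
    hs <- ss$heel_strikes
    vapply(seq_len(length(hs) - 1L), function(k) {
      to <- ss$toe_offs[ss$toe_offs > hs[k] & ss$toe_offs < hs[k + 1]]
      if (length(to)) 100 * (to[1] - hs[k]) / (hs[k + 1] - hs[k]) else NA_real_
    }, numeric(1))
  }
  stance_vals <- c(stance_pc(left), stance_pc(right))

  # DS per left stride: (contralateral TO - ipsilateral HS) +
  # (ipsilateral TO - contralateral HS), as % of that stride
  ds_for <- function(ipsi, contra) {
    hs <- ipsi$heel_strikes
    vapply(seq_len(length(hs) - 1L), function(k) {
      dur <- hs[k + 1] - hs[k]
      cto <- contra$toe_offs[contra$toe_offs > hs[k] & contra$toe_offs < hs[k + 1]]
      chs <- contra$heel_strikes[contra$heel_strikes > hs[k] & contra$heel_strikes < hs[k + 1]]
      ito <- ipsi$toe_offs[ipsi$toe_offs > hs[k] & ipsi$toe_offs < hs[k + 1]]
      if (length(cto) < 1 || length(chs) != 1 || length(ito) < 1) return(NA_real_)
      100 * ((cto[1] - hs[k]) + (ito[1] - chs)) / dur
    }, numeric(1))
  }
  ds_vals <- c(ds_for(left, right), ds_for(right, left))

  stride_all <- c(stride_l, stride_r)
  norm_div <- if (is.null(body_length_m) || !is.finite(body_length_m)) {
    warning("body length missing: dimensionless times not computed")
    NA_real_
  } else sqrt(body_length_m / 9.81)

  structure(list(
    strideT_values = stride_all, stepT_values = step_all,
    stanceT_values = stance_vals[!is.na(stance_vals)],
    DS_values = ds_vals[!is.na(ds_vals)],
    stride_left = stride_l, stride_right = stride_r,
    step_left = step_l[!is.na(step_l)], step_right = step_r[!is.na(step_r)],
    strideT = mean(stride_all), stepT = mean(step_all),
    nstrideT = mean(stride_all) / norm_div,
    nstepT = mean(step_all) / norm_div,
    stanceT = mean(stance_vals, na.rm = TRUE),
    DS = mean(ds_vals, na.rm = TRUE)
  ), class = "temporal_params")
}

#' Stride and step symmetry indices
#'
#' Relative absolute difference of the per-leg means:
#' `100 * |mean_left - mean_right| / (0.5 * (mean_left + mean_right))`.
#' Zero for perfectly symmetric gait; invariant under leg relabelling.
#'
#' @param left,right Lists with per-leg duration fragments: `$stride`
#'   (stride durations, s) and `$step` (step durations, s).
#' @return Named vector `c(symm_stride, symm_step)`.
#' @export
symmetry_indices <- function(left, right) {
  sym1 <- function(a, b) {
    if (!length(a) || !length(b))
      abort_gw("empty stride/step lists", "gaitwin_validation_error")
    100 * abs(mean(a) - mean(b)) / (0.5 * (mean(a) + mean(b)))
  }
  c(symm_stride = sym1(left$stride, right$stride),
    symm_step = sym1(left$step, right$step))
}

#' Poincare-plot variability of a stride-to-stride series
#'
#' Rotated-coordinate convention on the lag-1 Poincare plot: with
#' `d = (x[i+1] - x[i]) / sqrt(2)` and `s = (x[i+1] + x[i]) / sqrt(2)`,
#' `SD1` and `SD2` are the population standard deviations of `d` and `s`,
#' and `std = sqrt((SD1^2 + SD2^2) / 2)` is the population SD of the
#' plotted coordinates. The identity `SD1^2 + SD2^2 = 2 * std^2` then
#' holds exactly on every input.
#'
#' @param x Numeric series (length >= 3).
#' @return Named vector `c(SD1, SD2, std)` in the units of `x`.
#' @export
poincare <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L)
    abort_gw("need at least 3 points", "gaitwin_validation_error")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  d <- (x[-1] - x[-length(x)]) / sqrt(2)
  s <- (x[-1] + x[-length(x)]) / sqrt(2)
  sd1 <- pop_sd(d); sd2 <- pop_sd(s)
  c(SD1 = sd1, SD2 = sd2, std = sqrt((sd1^2 + sd2^2) / 2))
}
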