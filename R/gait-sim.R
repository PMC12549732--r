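#' Gait-signal generator parameters
#'
#' Parameters of the quasi-periodic walking model used to synthesize trunk
#' acceleration and shank angular velocity for one trial. Trunk
#' acceleration per axis is a per-stride harmonic series (harmonics of that
#' stride's fundamental, so cadence jitter propagates coherently) plus
#' white broadband noise. Shank angular velocity carries, per stride, one
#' dominant positive mid-swing peak with identifiable negative dips at
#' toe-off (before it) and heel strike (after it), placed at the
#' ground-truth event times.
#'
#' @param mean_stride_s Mean stride time (s). Toddler default 0.95 s.
#' @param stride_sd_s SD of stride time (s).
#' @param asymmetry Left/right step-time ratio (1 = symmetric).
#' @param stance_frac Stance duration as a fraction of the stride;
#'   double-support percentage is `2 * (100 * stance_frac - 50)` for
#'   symmetric gait.
#' @param harmonics Named list of per-axis harmonic amplitudes (m/s^2);
#'   element `k` is the amplitude of harmonic `k` of the stride frequency.
#'   Axes `v`, `ml`, `ap`. Vertical/antero-posterior power sits on even
#'   harmonics (two steps per stride), medio-lateral on odd.
#' @param noise_sd Broadband white-noise SD added to each trunk axis (m/s^2).
#' @param gyro_noise_sd White-noise SD on each gyro channel (deg/s).
#' @param duration_s Trial duration (s).
#' @param fs Sampling rate (Hz).
#' @return Object of class `gait_params`.
#' @export
gait_params <- function(mean_stride_s = 0.95, stride_sd_s = 0.045,
                        asymmetry = 1.0, stance_frac = 0.62,
                        harmonics = list(v = c(0.8, 2.0, 0.3, 0.6),
                                         ml = c(1.5, 0.4, 0.5, 0.15),
                                         ap = c(0.6, 1.5, 0.25, 0.45)),
                        noise_sd = 0.5, gyro_noise_sd = 0,
                        duration_s = 60, fs = 100) {
  if (mean_stride_s <= 0 || fs <= 0 || duration_s <= 0)
    abort_gw("mean_stride_s, fs and duration_s must be positive",
             "gaitwin_validation_error")
  if (stride_sd_s < 0 || noise_sd < 0 || gyro_noise_sd < 0)
    abort_gw("noise SDs must be >= 0", "gaitwin_validation_error")
  if (stance_frac <= 0.5 || stance_frac >= 1)
    abort_gw("stance_frac must lie in (0.5, 1)", "gaitwin_validation_error")
  structure(list(mean_stride_s = mean_stride_s, stride_sd_s = stride_sd_s,
                 asymmetry = asymmetry, stance_frac = stance_frac,
                 harmonics = harmonics, noise_sd = noise_sd,
                 gyro_noise_sd = gyro_noise_sd,
                 duration_s = duration_s, fs = fs),
            class = "gait_params")
}

#' Gait parameters for one child, with risk-group effect shifts
#'
#' Applies the cohort's high-risk effect shifts (longer stride, more
#' variable stride timing, more double support, more periodic and less
#' noisy trunk signal) on top of the base parameters, then adds small
#' per-child lognormal heterogeneity drawn from the child's derived RNG
#' stream.
#'
#' @param child One-row child record (needs `child_id` and `risk`).
#' @param base A [gait_params()] object.
#' @param effects Named list of shifts, e.g. [default_effect_sizes()].
#' @param master_seed Cohort master seed.
#' @return A `gait_params` object.
#' @export
child_gait_params <- function(child, base = gait_params(),
                              effects = default_effect_sizes(),
                              master_seed = 1L) {
  p <- base
  if (identical(child$risk, "high")) {
    p$mean_stride_s <- p$mean_stride_s * (effects$stride_mean_mult %||% 1)
    p$stride_sd_s <- p$stride_sd_s * (effects$stride_sd_mult %||% 1)
    p$stance_frac <- min(0.95, p$stance_frac + (effects$stance_frac_add %||% 0))
    p$harmonics <- lapply(p$harmonics, `*`, effects$harmonic_mult %||% 1)
    p$noise_sd <- p$noise_sd * (effects$noise_mult %||% 1)
  }
  with_seed(derive_seed(master_seed, paste0("gaitpar/", child$child_id)), {
    p$mean_stride_s <- p$mean_stride_s * exp(rnorm(1, 0, 0.04))
    p$stride_sd_s <- p$stride_sd_s * exp(rnorm(1, 0, 0.15))
    p$stance_frac <- min(0.95, max(0.52, p$stance_frac + rnorm(1, 0, 0.01)))
    p$asymmetry <- p$asymmetry * exp(rnorm(1, 0, 0.02))
  })
  p
}

#' Generate one synthetic gait trial
#'
#' Simulates a walking trial for one child: left/right heel-strike,
#' toe-off and mid-swing times from a jittered stride sequence, trunk
#' acceleration as a stride-locked harmonic series plus white noise, and
#' shank angular velocity as per-stride templates on the sagittal channel.
#' The returned `truth` annotation carries the exact event times, the
#' per-stride durations and the injected harmonic amplitudes, so every
#' downstream metric can be validated against ground truth.
#'
#' @param child One-row child record, or `NULL` for an anonymous trial.
#' @param params A [gait_params()] object.
#' @param seed Integer seed for this trial's RNG stream.
#' @param truth Keep the ground-truth annotation? If `TRUE` the trial must
#'   contain at least 10 complete strides.
#' @return Object of class `gait_trial`: `child_id`, `fs`, `time_s`,
#'   `trunk_acc` (matrix, columns v/ml/ap), `shank_gyro_left`,
#'   `shank_gyro_right` (matrices, columns x/y/z; z is sagittal), `truth`.
#' @export
generate_gait_trial <- function(child = NULL, params = gait_params(),
                                seed = 1L, truth = TRUE) {
  stopifnot(inherits(params, "gait_params"))
  child_id <- if (is.null(child)) "anon" else child$child_id
  with_seed(seed, build_trial(child_id, params, truth))
}

build_trial <- function(child_id, p, keep_truth) {
  fs <- p$fs
  n <- round(p$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs

  lead_in <- 0.5
  strides <- list(start = numeric(), dur = numeric())
  cur <- lead_in
  repeat {
    d <- max(0.4 * p$mean_stride_s, rnorm(1, p$mean_stride_s, p$stride_sd_s))
    if (cur + d > p$duration_s - 0.3) break
    strides$start <- c(strides$start, cur)
    strides$dur <- c(strides$dur, d)
    cur <- cur + d
  }
  ns <- length(strides$dur)
  if (keep_truth && ns < 10L)
    abort_gw(sprintf("trial too short: %d complete strides (< 10)", ns),
             "gaitwin_too_short_error")
  if (ns < 1L)
    abort_gw("trial too short for a single stride", "gaitwin_too_short_error")

  a <- p$asymmetry
  step_l <- strides$dur * a / (1 + a)     # left HS -> right HS
  end_t <- strides$start[ns] + strides$dur[ns]
  hs_l <- c(strides$start, end_t)         # ns + 1 events incl. terminal HS
  hs_r <- strides$start + step_l
  to_l <- strides$start + p$stance_frac * strides$dur
  # right stride k runs hs_r[k] .. hs_r[k+1]
  dur_r <- diff(hs_r)
  to_r <- hs_r[-length(hs_r)] + p$stance_frac * dur_r
  ms_l <- (to_l + hs_l[-1L]) / 2
  ms_r <- (to_r + hs_r[-1L]) / 2

  trunk <- sapply(c("v", "ml", "ap"), function(ax) {
    amps <- p$harmonics[[ax]] %||% numeric()
    x <- numeric(n)
    if (length(amps)) {
      idx <- findInterval(t, c(strides$start, end_t))
      inside <- idx >= 1L & idx <= ns & t < end_t & t >= strides$start[1L]
      k <- idx[inside]
      phase <- (t[inside] - strides$start[k]) / strides$dur[k]
      acc <- numeric(sum(inside))
      for (h in seq_along(amps))
        if (amps[h] != 0) acc <- acc + amps[h] * sin(2 * pi * h * phase)
      x[inside] <- acc
    }
    x + if (p$noise_sd > 0) rnorm(n, 0, p$noise_sd) else 0
  })
  colnames(trunk) <- c("v", "ml", "ap")

  gyro_l <- shank_template(t, hs_l, to_l, ms_l, strides$dur, p)
  gyro_r <- shank_template(t, hs_r, to_r, ms_r, c(dur_r, mean(strides$dur)), p)

  tr <- structure(list(
    child_id = child_id, fs = fs, time_s = t,
    trunk_acc = trunk, shank_gyro_left = gyro_l, shank_gyro_right = gyro_r,
    truth = NULL, params = p), class = "gait_trial")
  if (keep_truth)
    tr$truth <- list(
      left = list(heel_strikes = hs_l, toe_offs = to_l, mid_swings = ms_l),
      right = list(heel_strikes = hs_r, toe_offs = to_r, mid_swings = ms_r),
      stride_durations = strides$dur,
      harmonics = p$harmonics)
  tr
}

# Sagittal (z) channel: mid-swing Gaussian peak flanked by negative dips at
# toe-off and heel strike; x/y carry only low-level noise.
shank_template <- function(t, hs, to, ms, dur, p) {
  n <- length(t)
  z <- numeric(n)
  add_bump <- function(z, centre, amp, width) {
    lo <- max(1L, floor((centre - 4 * width) * p$fs) + 1L)
    hi <- min(n, ceiling((centre + 4 * width) * p$fs) + 1L)
    if (lo <= hi) {
      i <- lo:hi
      z[i] <- z[i] + amp * exp(-((t[i] - centre)^2) / (2 * width^2))
    }
    z
  }
  for (k in seq_along(ms)) {
    w <- dur[min(k, length(dur))]
    z <- add_bump(z, ms[k], 300, 0.06 * w)
    if (k <= length(to)) z <- add_bump(z, to[k], -200, 0.025 * w)
  }
  for (k in seq_along(hs)[-1L]) z <- add_bump(z, hs[k], -200, 0.025 * dur[min(k - 1L, length(dur))])
  noise <- function() if (p$gyro_noise_sd > 0) rnorm(n, 0, p$gyro_noise_sd) else numeric(n)
  out <- cbind(x = 10 * sin(2 * pi * t / 3) + noise(),
               y = noise(),
               z = z + noise())
  out
}

#' Write / read one gait trial as CSV plus a JSON sidecar
#'
#' The CSV holds the sampled series (`time_s, trunk_v, trunk_ml, trunk_ap,
#' gyroL_x/y/z, gyroR_x/y/z`); the sidecar JSON holds the sampling rate,
#' child id and ground-truth annotation.
#'
#' @param trial A `gait_trial`.
#' @param csv_path,json_path Output paths.
#' @return `csv_path` invisibly (writer); a `gait_trial` (reader).
#' @export
write_trial_csv <- function(trial, csv_path, json_path) {
  df <- data.frame(time_s = trial$time_s,
                   trunk_v = trial$trunk_acc[, "v"],
                   trunk_ml = trial$trunk_acc[, "ml"],
                   trunk_ap = trial$trunk_acc[, "ap"],
                   gyroL_x = trial$shank_gyro_left[, "x"],
                   gyroL_y = trial$shank_gyro_left[, "y"],
                   gyroL_z = trial$shank_gyro_left[, "z"],
                   gyroR_x = trial$shank_gyro_right[, "x"],
                   gyroR_y = trial$shank_gyro_right[, "y"],
                   gyroR_z = trial$shank_gyro_right[, "z"])
  write.csv(df, csv_path, row.names = FALSE)
  meta <- list(child_id = trial$child_id, fs = trial$fs, truth = trial$truth)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(csv_path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(csv_path, json_path) {
  df <- read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(
    child_id = meta$child_id, fs = meta$fs, time_s = df$time_s,
    trunk_acc = as.matrix(`colnames<-`(df[c("trunk_v", "trunk_ml", "trunk_ap")],
                                       c("v", "ml", "ap"))),
    shank_gyro_left = as.matrix(`colnames<-`(df[c("gyroL_x", "gyroL_y", "gyroL_z")],
                                             c("x", "y", "z"))),
    shank_gyro_right = as.matrix(`colnames<-`(df[c("gyroR_x", "gyroR_y", "gyroR_z")],
                                              c("x", "y", "z"))),
    truth = meta$truth, params = NULL), class = "gait_trial")
}
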