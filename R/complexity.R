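#' Configuration for the complexity and automaticity metrics
#'
#' Parameters of sample entropy, multiscale coarse-graining, recurrence
#' quantification and the harmonic ratio. The defaults are the field's
#' standard choices: `m = 2`, tolerance `0.2 * SD`, scales 1..6 for
#' entropy; embedding `(5, 10)`, radius `0.2 * SD`, Euclidean norm,
#' Theiler window 1 and minimal line length 2 for RQA; 20 harmonics for
#' the harmonic ratio.
#'
#' @param m Embedding length for sample entropy.
#' @param r_frac Tolerance as a fraction of the scale-1 (original) series SD.
#' @param scales Coarse-graining scales.
#' @param rqa_dim,rqa_delay Time-delay embedding dimension and delay (samples).
#' @param rqa_radius_frac Recurrence radius as a fraction of the series SD.
#' @param lmin Minimal diagonal line length.
#' @param theiler Excluded diagonal band half-width.
#' @param hr_harmonics Number of stride-frequency harmonics for the HR.
#' @param hr_cap Cap for the harmonic ratio when its denominator vanishes.
#' @param hr_eps_den Denominator threshold triggering the cap.
#' @return Object of class `complexity_config`.
#' @export
complexity_config <- function(m = 2L, r_frac = 0.2, scales = 1:6,
                              rqa_dim = 5L, rqa_delay = 10L,
                              rqa_radius_frac = 0.2, lmin = 2L, theiler = 1L,
                              hr_harmonics = 20L, hr_cap = 20,
                              hr_eps_den = 1e-8) {
  if (m < 1L || r_frac <= 0 || !length(scales) || any(scales < 1) ||
      rqa_dim < 2L || lmin < 2L)
    abort_gw("invalid complexity configuration", "gaitwin_validation_error")
  structure(list(m = as.integer(m), r_frac = r_frac,
                 scales = as.integer(scales), rqa_dim = as.integer(rqa_dim),
                 rqa_delay = as.integer(rqa_delay),
                 rqa_radius_frac = rqa_radius_frac, lmin = as.integer(lmin),
                 theiler = as.integer(theiler),
                 hr_harmonics = as.integer(hr_harmonics), hr_cap = hr_cap,
                 hr_eps_den = hr_eps_den), class = "complexity_config")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sample entropy
#'
#' `SampEn(m, r)` of a series: with `B` the number of template pairs
#' (`i < j`) within Chebyshev tolerance `r_abs` at length `m`, and `A` the
#' same at length `m + 1` (self-matches excluded), the entropy is
#' `-ln(A / B)`. When either count is zero the value is undefined and
#' `NaN` is returned with a warning.
#'
#' @param x Numeric series, length > `m + 1`.
#' @param m Template length.
#' @param r_abs Absolute tolerance (same units as `x`).
#' @return Scalar entropy (nats); `NaN` when undefined.
#' @export
sample_entropy <- function(x, m = 2L, r_abs) {
  x <- as.numeric(x)
  if (length(x) <= m + 1L)
    abort_gw("series too short for sample entropy",
             "gaitwin_validation_error")
  if (r_abs <= 0)
    abort_gw("r_abs must be positive", "gaitwin_validation_error")
  cnt <- sampen_counts_cpp(x, as.integer(m), r_abs)
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) {
    warning("sample entropy undefined: no template matches at m or m+1")
    return(NaN)
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Coarse-grain a series for multiscale entropy
#'
#' Means of consecutive non-overlapping windows of length `tau`; a
#' trailing remainder shorter than `tau` is dropped.
#'
#' @param x Numeric series.
#' @param tau Scale (window length, samples).
#' @return The coarse-grained series.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  nw <- length(x) %/% tau
  if (nw == 0L) return(numeric())
  colMeans(matrix(x[seq_len(nw * tau)], nrow = tau))
}

#' Multiscale sample entropy
#'
#' Sample entropy of the coarse-grained series at each scale. The
#' tolerance is fixed from the scale-1 (original) series SD for all
#' scales, so the entropy decrease of white noise under coarse-graining
#' is preserved.
#'
#' @param x Numeric series.
#' @param cfg A [complexity_config()].
#' @return Named vector `sen_1 .. sen_K`; scales whose coarse-grained
#'   series is too short yield `NA` with a warning.
#' @export
multiscale_entropy <- function(x, cfg = complexity_config()) {
  x <- as.numeric(x)
  r_abs <- cfg$r_frac * pop_sd(x)
  out <- vapply(cfg$scales, function(tau) {
    cg <- coarse_grain(x, tau)
    if (length(cg) <= cfg$m + 1L) {
      warning(sprintf("scale %d: coarse-grained series too short", tau))
      return(NA_real_)
    }
    if (r_abs <= 0) return(0)  # constant series: perfectly regular
    sample_entropy(cg, cfg$m, r_abs)
  }, numeric(1))
  names(out) <- paste0("sen_", cfg$scales)
  out
}

#' Recurrence quantification analysis
#'
#' Time-delay embeds `x`, thresholds the Euclidean distance matrix at
#' `rqa_radius_frac * SD(x)` (Theiler band excluded) and summarises the
#' upper triangle: recurrence rate `RR`, determinism `DET` (fraction of
#' recurrent points on diagonals of length >= `lmin`) and average diagonal
#' length `AvgL`. A zero-variance series returns the documented degenerate
#' convention `RR = 1, DET = 1, AvgL = ` longest admissible diagonal.
#'
#' @param x Numeric series, length >= `rqa_dim * rqa_delay + 10`.
#' @param cfg A [complexity_config()].
#' @return Named vector `c(RR, DET, AvgL)`.
#' @export
rqa <- function(x, cfg = complexity_config()) {
  x <- as.numeric(x)
  if (length(x) < cfg$rqa_dim * cfg$rqa_delay + 10L)
    abort_gw("series too short for RQA", "gaitwin_validation_error")
  ne <- length(x) - (cfg$rqa_dim - 1L) * cfg$rqa_delay
  s <- pop_sd(x)
  if (s == 0) {
    return(c(RR = 1, DET = 1, AvgL = ne - (cfg$theiler + 1L)))
  }
  st <- rqa_stats_cpp(x, cfg$rqa_dim, cfg$rqa_delay,
                      cfg$rqa_radius_frac * s, cfg$theiler, cfg$lmin)
  rr <- st$rec / st$npairs
  det <- if (st$rec > 0) st$pts_on_lines / st$rec else 0
  avgl <- if (st$nlines > 0) st$sumlen / st$nlines else NA_real_
  c(RR = rr, DET = det, AvgL = avgl)
}

#' Harmonic ratio of trunk acceleration
#'
#' Per stride (delimited by successive heel strikes of one leg), the
#' detrended acceleration segment is decomposed into Fourier amplitudes at
#' harmonics 1..K of that stride's fundamental. For the vertical and
#' antero-posterior axes the ratio is the summed even over summed odd
#' amplitudes (locomotion puts two steps in one stride, so a smooth
#' pattern concentrates power on even harmonics); for the medio-lateral
#' axis the convention is reciprocal (odd over even). The per-stride
#' ratios are averaged; a vanishing denominator caps the ratio at
#' `hr_cap` with a `capped` attribute.
#'
#' @param acc Trunk-acceleration series for one axis (m/s^2).
#' @param stride_events Heel-strike times (s) of one leg; at least 4
#'   (3 complete strides).
#' @param axis `"V"`, `"ML"` or `"AP"` (case-insensitive).
#' @param fs Sampling rate (Hz).
#' @param cfg A [complexity_config()].
#' @return Mean harmonic ratio across strides (attribute `capped` counts
#'   capped strides).
#' @export
harmonic_ratio <- function(acc, stride_events, axis, fs,
                           cfg = complexity_config()) {
  axis <- tolower(axis)
  if (!axis %in% c("v", "ml", "ap"))
    abort_gw("axis must be V, ML or AP", "gaitwin_validation_error")
  ev <- sort(as.numeric(stride_events))
  if (length(ev) < 4L)
    abort_gw("need at least 3 complete strides", "gaitwin_validation_error")
  n_capped <- 0L
  ratios <- vapply(seq_len(length(ev) - 1L), function(k) {
    i0 <- round(ev[k] * fs) + 1L
    i1 <- round(ev[k + 1] * fs)
    if (i1 > length(acc) || i1 - i0 + 1L < 8L) return(NA_real_)
    seg <- acc[i0:i1]
    nseg <- length(seg)
    idx <- seq_len(nseg) - 1L
    seg <- seg - mean(seg)  # remove DC; bins k >= 1 are unaffected by it
    kmax <- min(cfg$hr_harmonics, (nseg - 1L) %/% 2L)
    h <- seq_len(kmax)
    amp <- vapply(h, function(hh)
      Mod(sum(seg * exp(-2i * pi * hh * idx / nseg))) * 2 / nseg, numeric(1))
    even <- sum(amp[h %% 2 == 0]); odd <- sum(amp[h %% 2 == 1])
    num <- if (axis == "ml") odd else even
    den <- if (axis == "ml") even else odd
    if (den < cfg$hr_eps_den) {
      n_capped <<- n_capped + 1L
      return(cfg$hr_cap)
    }
    num / den
  }, numeric(1))
  out <- mean(ratios, na.rm = TRUE)
  attr(out, "capped") <- n_capped
  out
}
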