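#' Cohort simulation specification
#'
#' Describes the composition of a synthetic toddler cohort: how many
#' preterm and full-term children to draw, the gestational-age (GA)
#' distributions, the birth-weight-given-GA model and the group-level
#' effect shifts applied to the gait generator for high-risk children.
#'
#' The defaults emulate a 46-child proof-of-concept cohort: 29 preterm
#' (GA 23-36 wk, weighted towards moderate prematurity so that the
#' expected number of high-risk children is close to 8 of 46) and 17
#' full-term controls. Birth weight given GA is linear-Gaussian
#' (`bw_base_g + bw_slope_g_per_wk * (GA - 22)`, SD `bw_sd_g`, floored
#' at `bw_floor_g`); the constants are configuration, not claims about
#' any real sample.
#'
#' @param n_preterm,n_fullterm Number of children per group.
#' @param ga_preterm_range Integer GA range (weeks) for preterm draws.
#' @param ga_fullterm_mean,ga_fullterm_sd Full-term GA distribution (weeks),
#'   truncated to `[37, 42]` and rounded to whole weeks.
#' @param bw_base_g,bw_slope_g_per_wk,bw_sd_g,bw_floor_g Birth-weight model.
#' @param miss_rate_cog Probability that a child's cognitive score is missing.
#' @param effect_sizes Named list of multiplicative/additive shifts applied to
#'   the gait-generator parameters of high-risk children; see
#'   [default_effect_sizes()].
#' @param seed Master seed; per-child streams are derived by stable hashing
#'   of `(seed, child_id)`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_preterm = 29L, n_fullterm = 17L,
                        ga_preterm_range = c(23L, 36L),
                        ga_fullterm_mean = 39.5, ga_fullterm_sd = 1.2,
                        bw_base_g = 500, bw_slope_g_per_wk = 180,
                        bw_sd_g = 250, bw_floor_g = 350,
                        miss_rate_cog = 0.05,
                        effect_sizes = default_effect_sizes(),
                        seed = 1L) {
  if (!is_count(n_preterm) || !is_count(n_fullterm))
    abort_gw("n_preterm and n_fullterm must be non-negative counts",
             "gaitwin_validation_error")
  if (any(ga_preterm_range < 22) || any(ga_preterm_range > 42) ||
      ga_fullterm_mean < 22 || ga_fullterm_mean > 42)
    abort_gw("gestational-age ranges must lie within [22, 42] weeks",
             "gaitwin_validation_error")
  if (bw_sd_g < 0)
    abort_gw("noise SDs must be >= 0", "gaitwin_validation_error")
  structure(list(
    n_preterm = as.integer(n_preterm), n_fullterm = as.integer(n_fullterm),
    ga_preterm_range = as.integer(ga_preterm_range),
    ga_fullterm_mean = ga_fullterm_mean, ga_fullterm_sd = ga_fullterm_sd,
    bw_base_g = bw_base_g, bw_slope_g_per_wk = bw_slope_g_per_wk,
    bw_sd_g = bw_sd_g, bw_floor_g = bw_floor_g,
    miss_rate_cog = miss_rate_cog,
    effect_sizes = effect_sizes, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default high-risk effect shifts for the gait generator
#'
#' High-risk children are generated with a longer mean stride time, larger
#' stride-time variability, more double support (via a higher stance
#' fraction), a more periodic trunk signal (stronger stride harmonics,
#' weaker broadband noise) and slightly lower cognitive score and walking
#' experience. These directions make the downstream effect-direction
#' analyses recoverable against ground truth; the magnitudes are
#' configuration.
#'
#' @return Named list of shifts.
#' @export
default_effect_sizes <- function() {
  list(
    stride_mean_mult = 1.08,   # longer (normalized) stride time
    stride_sd_mult   = 1.60,   # higher stride-time variability (SD1/std)
    stance_frac_add  = 0.03,   # +3 % stance -> +6 % double support
    harmonic_mult    = 1.20,   # more periodic trunk acceleration
    noise_mult       = 0.50,   # less broadband complexity
    cog_shift        = -8,     # BSID-III points
    walk_exp_shift   = -6      # weeks of walking experience
  )
}

#' Assign the clinical risk label
#'
#' A child is labelled high risk when born at 28 or fewer gestational weeks
#' and/or with a birth weight of 1000 g or less; all other children
#' (preterm and full-term) are low risk.
#'
#' @param ga_weeks Gestational age at birth in weeks (positive).
#' @param bw_g Birth weight in grams (positive).
#' @return `"high"` or `"low"` (vectorised).
#' @export
assign_risk_label <- function(ga_weeks, bw_g) {
  if (any(!is.finite(ga_weeks)) || any(!is.finite(bw_g)) ||
      any(ga_weeks <= 0) || any(bw_g <= 0))
    abort_gw("ga_weeks and bw_g must be positive and finite",
             "gaitwin_validation_error")
  ifelse(ga_weeks <= 28 | bw_g <= 1000, "high", "low")
}

#' Generate a synthetic cohort of clinical records
#'
#' Draws one `ChildRecord` row per child. Preterm GA is sampled on the
#' integer grid `ga_preterm_range` with sampling weights proportional to
#' `sqrt(GA - 22)`, which concentrates mass at moderate prematurity so the
#' expected high-risk fraction is close to 8/46 under the default
#' birth-weight model. All covariates are drawn from per-child RNG streams
#' derived by hashing `(seed, child_id)`, so records are reproducible
#' child-by-child.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with one row per child: `child_id, sex, ga_weeks,
#'   twin, bw_g, length_birth_cm, length_t24_cm, weight_t24_g,
#'   walk_exp_weeks, cog_score, group, risk`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_preterm + spec$n_fullterm
  if (n == 0L)
    return(empty_cohort())
  groups <- c(rep("preterm", spec$n_preterm), rep("fullterm", spec$n_fullterm))
  ids <- sprintf("child-%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    with_seed(derive_seed(spec$seed, paste0("clinical/", ids[i])),
              draw_child(ids[i], groups[i], spec))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

empty_cohort <- function() {
  data.frame(child_id = character(), sex = character(), ga_weeks = numeric(),
             twin = logical(), bw_g = numeric(), length_birth_cm = numeric(),
             length_t24_cm = numeric(), weight_t24_g = numeric(),
             walk_exp_weeks = numeric(), cog_score = numeric(),
             group = character(), risk = character(),
             stringsAsFactors = FALSE)
}

draw_child <- function(id, group, spec) {
  if (group == "preterm") {
    grid <- seq(spec$ga_preterm_range[1], spec$ga_preterm_range[2])
    ga <- sample(grid, 1L, prob = sqrt(grid - 22))
    twin <- runif(1) < 0.25
  } else {
    ga <- round(min(42, max(37, rnorm(1, spec$ga_fullterm_mean,
                                      spec$ga_fullterm_sd))))
    twin <- runif(1) < 0.05
  }
  bw <- max(spec$bw_floor_g,
            rnorm(1, spec$bw_base_g + spec$bw_slope_g_per_wk * (ga - 22),
                  spec$bw_sd_g))
  risk <- assign_risk_label(ga, bw)
  eff <- spec$effect_sizes
  cog_mu <- if (group == "fullterm") 105 else 100
  walk_mu <- if (group == "fullterm") 50 else 44
  if (risk == "high") {
    cog_mu <- cog_mu + (eff$cog_shift %||% 0)
    walk_mu <- walk_mu + (eff$walk_exp_shift %||% 0)
  }
  cog <- round(rnorm(1, cog_mu, 12))
  if (runif(1) < spec$miss_rate_cog) cog <- NA_real_
  data.frame(
    child_id = id,
    sex = sample(c("F", "M"), 1L),
    ga_weeks = ga,
    twin = twin,
    bw_g = round(bw),
    length_birth_cm = round(24 + 1.45 * (ga - 22) + rnorm(1, 0, 2), 1),
    length_t24_cm = round(rnorm(1, if (risk == "high") 84 else 86, 3), 1),
    weight_t24_g = round(rnorm(1, if (risk == "high") 11200 else 12000, 1200)),
    walk_exp_weeks = round(max(10, rnorm(1, walk_mu, 7))),
    cog_score = cog,
    group = group,
    risk = risk,
    stringsAsFactors = FALSE
  )
}

#' Write / read a cohort table as CSV
#'
#' One row per child, fixed header, UTF-8, `.` decimal separator.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly (writer); the cohort `data.frame` (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$twin <- as.logical(df$twin)
  df
}
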