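test_that("noise-free synthetic trials are segmented to within one sample of truth", {
  p <- gait_params(stride_sd_s = 0, noise_sd = 0, duration_s = 25,
                   mean_stride_s = 1.0)
  tr <- generate_gait_trial(NULL, p, seed = 2)
  ev <- detect_gait_events(tr$shank_gyro_left, tr$fs, leg = "left")
  expect_gte(length(ev$mid_swings), 20)
  err <- vapply(ev$heel_strikes, function(h)
    min(abs(tr$truth$left$heel_strikes - h)), numeric(1))
  expect_lte(max(err) * tr$fs, 1)
})

test_that("events stay within three samples of truth under gyro noise", {
  errs <- vapply(1:20, function(s) {
    p <- gait_params(stride_sd_s = 0.03, noise_sd = 0, gyro_noise_sd = 10,
                     duration_s = 20)
    tr <- generate_gait_trial(NULL, p, seed = s)
    ev <- detect_gait_events(tr$shank_gyro_left, tr$fs, leg = "left")
    max(vapply(ev$heel_strikes, function(h)
      min(abs(tr$truth$left$heel_strikes - h)), numeric(1)))
  }, numeric(1))
  expect_lte(max(errs) * 100, 3)
})

test_that("degenerate inputs raise classed detection errors", {
  expect_error(detect_gait_events(rep(0, 1000), 100),
               class = "gaitwin_no_strides_error")
  one_burst <- c(rep(0, 300), 100 * exp(-((1:100) - 50)^2 / 50), rep(0, 300))
  expect_error(detect_gait_events(one_burst, 100),
               class = "gaitwin_insufficient_strides_error")
  expect_error(detect_gait_events(rep(0, 50), 100),
               class = "gaitwin_validation_error")
})

test_that("temporal parameters reproduce the hand-computed example", {
  # left HS at 0,1,2,...; left TO at 0.62 + k; right HS at 0.5 + k;
  # right TO at 0.12 + k  ->  strideT 1.0, stepT 0.5, stanceT 62 %, DS 24 %
  k <- 0:9
  left <- stride_series_from_times("left", hs = k, to = 0.62 + head(k, -1))
  right <- stride_series_from_times("right", hs = 0.5 + head(k, -1),
                                    to = 0.12 + head(k, -1))
  tp <- temporal_parameters(left, right, body_length_m = 0.80)
  expect_equal(tp$strideT, 1.0, tolerance = 1e-9)
  expect_equal(tp$stepT, 0.5, tolerance = 1e-9)
  expect_equal(tp$stanceT, 62, tolerance = 1e-6)
  expect_equal(tp$DS, 24, tolerance = 1e-6)
  expect_equal(tp$nstrideT, 1.0 / sqrt(0.80 / 9.81), tolerance = 1e-6)
  expect_true(all(abs(tp$strideT_values - 1.0) < 1e-9))

  # missing body length: dimensionless times absent, with a warning
  expect_warning(tp2 <- temporal_parameters(left, right, NULL),
                 "body length")
  expect_true(is.na(tp2$nstrideT))
})

test_that("temporal outputs are invariant to a constant time offset", {
  k <- 0:9
  mk <- function(off) list(
    l = stride_series_from_times("left", k + off, 0.62 + head(k, -1) + off),
    r = stride_series_from_times("right", 0.5 + head(k, -1) + off,
                                 0.12 + head(k, -1) + off))
  a <- mk(0); b <- mk(17.3)
  ta <- temporal_parameters(a$l, a$r, 0.85)
  tb <- temporal_parameters(b$l, b$r, 0.85)
  for (f in c("strideT", "stepT", "stanceT", "DS", "nstrideT"))
    expect_equal(ta[[f]], tb[[f]], tolerance = 1e-9)
})

test_that("non-interleaved event sequences are rejected", {
  k <- 0:9
  left <- stride_series_from_times("left", k, 0.62 + head(k, -1))
  far <- stride_series_from_times("right", 100 + k, 100.62 + head(k, -1))
  expect_error(temporal_parameters(left, far, 0.8),
               class = "gaitwin_event_sequence_error")
})

test_that("symmetry indices follow the relative-difference formula and are leg-invariant", {
  same <- list(stride = rep(1, 5), step = rep(0.5, 5))
  expect_equal(unname(symmetry_indices(same, same)), c(0, 0))
  l <- list(stride = rep(1.1, 6), step = rep(0.55, 6))
  r <- list(stride = rep(0.9, 6), step = rep(0.45, 6))
  expect_equal(symmetry_indices(l, r)[["symm_stride"]], 20, tolerance = 1e-9)
  expect_equal(symmetry_indices(l, r), symmetry_indices(r, l))
  expect_error(symmetry_indices(list(stride = numeric(), step = 1), r),
               class = "gaitwin_validation_error")
})

test_that("Poincare metrics match closed forms and satisfy the Pythagoras identity", {
  expect_equal(unname(poincare(rep(1, 10))), c(0, 0, 0))
  alt <- rep(c(0.9, 1.1), length.out = 101)  # even number of differences
  pc <- poincare(alt)
  expect_equal(pc[["SD1"]], 0.2 / sqrt(2), tolerance = 1e-12)
  expect_equal(pc[["SD2"]], 0, tolerance = 1e-12)
  expect_equal(pc[["std"]], 0.1, tolerance = 1e-12)

  set.seed(7)
  g <- rnorm(10000)
  pg <- poincare(g)
  expect_equal(pg[["SD1"]], 1, tolerance = 0.05)
  expect_equal(pg[["SD2"]], 1, tolerance = 0.05)

  for (i in 1:25) {
    x <- switch(1 + i %% 3, rnorm(3 + i), cumsum(rnorm(10 + i)),
                rep(c(0, 1), length.out = 5 + i))
    p <- poincare(x)
    expect_equal(p[["SD1"]]^2 + p[["SD2"]]^2, 2 * p[["std"]]^2,
                 tolerance = 1e-9)
  }
  expect_error(poincare(c(1, 2)), class = "gaitwin_validation_error")
})
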