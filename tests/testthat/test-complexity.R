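test_that("sample entropy equals the brute-force enumeration", {
  x <- c(1, 2, 3, 2, 1, 2, 3, 2, 1)
  expect_equal(sample_entropy(x, 2, 0.5), sampen_bruteforce(x, 2, 0.5),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:8) {
    y <- runif(sample(60:250, 1))
    r <- 0.2 * sd(y)
    expect_equal(sample_entropy(y, 2, r), sampen_bruteforce(y, 2, r),
                 tolerance = 1e-12)
  }
  expect_error(sample_entropy(c(1, 2, 3), 2, 0.1),
               class = "gaitwin_validation_error")
  expect_warning(v <- sample_entropy(seq(1, 100, by = 1), 2, 1e-6),
                 "undefined")
  expect_true(is.nan(v))
})

test_that("constant series have zero entropy at every scale", {
  expect_equal(sample_entropy(rep(3, 50), 2, 0.5), 0)
  expect_true(all(multiscale_entropy(rep(2, 200)) == 0))
})

test_that("coarse-graining averages non-overlapping windows", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(1:7, 3), c(2, 5))  # remainder dropped
  expect_equal(coarse_grain(1:5, 1), as.numeric(1:5))
})

test_that("multiscale entropy shows the standard white-vs-correlated-noise signature", {
  set.seed(21)
  w <- rnorm(4000)
  mw <- multiscale_entropy(w)
  expect_true(all(diff(mw) < 0))  # white noise decays with scale
  ar <- as.numeric(stats::filter(rnorm(4000), rep(1 / 4, 4), sides = 1))
  ar <- ar[!is.na(ar)]
  ar <- ar / sd(ar)  # match scale-1 variance
  mar <- multiscale_entropy(ar)
  expect_gt(mar[["sen_3"]], mw[["sen_3"]])
})

test_that("RQA equals the brute-force recurrence matrix reference", {
  cfg <- complexity_config()
  set.seed(31)
  for (i in 1:6) {
    x <- switch(1 + i %% 3,
                rnorm(sample(100:200, 1)),
                sin(2 * pi * (1:150) / 25) + rnorm(150, 0, 0.1),
                cumsum(rnorm(120)))
    got <- rqa(x, cfg)
    s <- sqrt(mean((x - mean(x))^2))
    want <- rqa_bruteforce(x, cfg$rqa_dim, cfg$rqa_delay,
                           cfg$rqa_radius_frac * s, cfg$theiler, cfg$lmin)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("RQA degenerate and periodic conventions hold", {
  cfg <- complexity_config()
  const <- rqa(rep(1, 100), cfg)
  expect_equal(const[["RR"]], 1)
  expect_equal(const[["DET"]], 1)
  s <- sin(2 * pi * (0:499) / 50)
  per <- rqa(s, cfg)
  expect_gte(per[["DET"]], 0.95)
  expect_error(rqa(rnorm(20), cfg), class = "gaitwin_validation_error")
})

test_that("entropy and RQA are invariant to affine transforms of the input", {
  set.seed(41)
  x <- rnorm(400)
  y <- 3.7 * x - 11
  cfg <- complexity_config()
  expect_equal(multiscale_entropy(x, cfg), multiscale_entropy(y, cfg),
               tolerance = 1e-9)
  expect_equal(rqa(x, cfg), rqa(y, cfg), tolerance = 1e-9)
})

test_that("harmonic ratio closed forms and monotonicity in even content", {
  p0 <- gait_params(stride_sd_s = 0, mean_stride_s = 1.0, noise_sd = 0,
                    duration_s = 25, harmonics = list(v = c(1)))
  tr0 <- generate_gait_trial(NULL, p0, seed = 3)
  expect_lt(harmonic_ratio(tr0$trunk_acc[, "v"],
                           tr0$truth$left$heel_strikes, "V", tr0$fs), 1e-6)
  hrs <- vapply(c(0.5, 1, 2, 4), function(a2) {
    p <- gait_params(stride_sd_s = 0, mean_stride_s = 1.0, noise_sd = 0,
                     duration_s = 25, harmonics = list(v = c(1, a2)))
    tr <- generate_gait_trial(NULL, p, seed = 3)
    as.numeric(harmonic_ratio(tr$trunk_acc[, "v"],
                              tr$truth$left$heel_strikes, "V", tr$fs))
  }, numeric(1))
  expect_equal(hrs, c(0.5, 1, 2, 4), tolerance = 0.05)
  expect_true(all(diff(hrs) > 0))
  expect_error(harmonic_ratio(rnorm(100), c(0, 1), "V", 100),
               class = "gaitwin_validation_error")
  expect_error(harmonic_ratio(rnorm(100), 0:5, "Q", 100),
               class = "gaitwin_validation_error")
})

test_that("metric vector schema is complete and protects the label-defining variables", {
  fx <- fixture_dir()
  co <- read_cohort_csv(file.path(fx, "cohort.csv"))
  tr <- read_trial_csv(file.path(fx, "trials", "child-003.csv"),
                       file.path(fx, "trials", "child-003.json"))
  m <- extract_trial_metrics(tr, co[3, ])
  expect_true(all(metric_schema() %in% names(m)))
  expect_false(any(c("ga_weeks", "bw_g") %in% names(m)))
  expect_equal(m$child_id, "child-003")
  expect_true(all(c(m$RR_v, m$RR_ml, m$RR_ap) >= 0 &
                  c(m$RR_v, m$RR_ml, m$RR_ap) <= 1))
  expect_true(all(c(m$DET_v, m$DET_ml, m$DET_ap) >= 0 &
                  c(m$DET_v, m$DET_ml, m$DET_ap) <= 1))
  expect_true(all(m[paste0("SEN_v_", 1:6)] >= 0, na.rm = TRUE))
  expect_true(m$HR_v >= 0)
  expect_error(
    assemble_metric_vector(NULL, list(), list(), c(symm_stride = 0, symm_step = 0),
                           list(), list(), list(ga_weeks = 30)),
    class = "gaitwin_validation_error")
})

test_that("a child without body length still yields a valid vector (nstrideT missing)", {
  fx <- fixture_dir()
  co <- read_cohort_csv(file.path(fx, "cohort.csv"))
  child <- co[4, ]
  child$length_t24_cm <- NA
  tr <- read_trial_csv(file.path(fx, "trials", "child-004.csv"),
                       file.path(fx, "trials", "child-004.json"))
  m <- extract_trial_metrics(tr, child)
  expect_true(is.na(m$nstrideT))
  expect_false(is.na(m$strideT))
})
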