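test_that("imputation fills by the column statistic over observed values only", {
  t1 <- impute(data.frame(a = c(1, NA, 3)), "mean")
  expect_equal(t1$a, c(1, 2, 3))
  t2 <- impute(data.frame(a = c(1, NA, 3, 100)), "median")
  expect_equal(t2$a[2], 3)
  t3 <- impute(data.frame(a = 1:3), "mean")
  expect_equal(t3$a, 1:3)
  expect_false(any(attr(t3, "imputed")))
  expect_true(attr(t1, "imputed")[2, 1])
  expect_error(impute(data.frame(a = c(NA_real_, NA_real_)), "mean"),
               class = "gaitwin_validation_error")
})

test_that("min-max scaling maps to [0,1], flags constants and inverts exactly", {
  r <- minmax_scale(data.frame(x = c(0, 5, 10)))
  expect_equal(r$scaled$x, c(0, 0.5, 1))
  expect_warning(rc <- minmax_scale(data.frame(x = c(2, 2, 2))), "constant")
  expect_equal(rc$scaled$x, c(0, 0, 0))
  set.seed(5)
  X <- data.frame(a = rnorm(20), b = runif(20, -3, 9))
  r2 <- minmax_scale(X)
  expect_true(all(as.matrix(r2$scaled) >= 0 & as.matrix(r2$scaled) <= 1))
  expect_equal(minmax_unscale(r2$scaled, r2$params), X, tolerance = 1e-12)
  expect_error(minmax_scale(data.frame(a = c(1, NA))),
               class = "gaitwin_validation_error")
})

test_that("class weights are inversely proportional to frequencies", {
  w <- class_weights(rep(c("low", "high"), c(38, 8)))
  expect_equal(w[["low"]], 46 / 76, tolerance = 1e-12)
  expect_equal(w[["high"]], 46 / 16, tolerance = 1e-12)
  expect_equal(sum(w * c(high = 8, low = 38)[names(w)]), 46)
  wb <- class_weights(rep(c("a", "b"), 10))
  expect_equal(unname(wb), c(1, 1))
  expect_error(class_weights(rep("a", 5)), class = "gaitwin_validation_error")
})

test_that("SMOTE balances classes by interpolation between minority neighbours", {
  X <- rbind(matrix(rnorm(38 * 2), 38), matrix(rnorm(8 * 2, 5), 8))
  y <- rep(c("low", "high"), c(38, 8))
  out <- smote_oversample(X, y, k_neighbors = 5, seed = 3)
  expect_equal(unname(table(out$y)["high"]), 38)
  expect_equal(unname(table(out$y)["low"]), 38)
  expect_equal(sum(out$synthetic), 30)
  out2 <- smote_oversample(X, y, k_neighbors = 5, seed = 3)
  expect_identical(out, out2)
  # on-the-segment geometry: with two diagonal minority points every
  # synthetic point has equal coordinates
  Xg <- rbind(matrix(rnorm(10 * 2), 10), c(0, 0), c(1, 1))
  yg <- c(rep("maj", 10), "min", "min")
  og <- smote_oversample(Xg, yg, k_neighbors = 1, seed = 2)
  syn <- og$X[og$synthetic, , drop = FALSE]
  expect_true(all(abs(syn[, 1] - syn[, 2]) < 1e-12))
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))
  expect_error(smote_oversample(X, y, k_neighbors = 8, seed = 1),
               class = "gaitwin_validation_error")
})

test_that("2-D embedding separates well-separated blobs and is deterministic", {
  set.seed(13)
  X <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, mean = 8), 30))
  lab <- rep(1:2, each = 30)
  e <- embed_2d(X, seed = 1, perplexity = 8, n_iter = 300)
  d <- as.matrix(dist(e$Y))
  sil <- mean(vapply(seq_len(60), function(i) {
    same <- which(lab == lab[i]); same <- same[same != i]
    a <- mean(d[i, same]); b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_gt(sil, 0.5)
  e2 <- embed_2d(X, seed = 1, perplexity = 8, n_iter = 300)
  expect_identical(e$Y, e2$Y)
  # duplicated rows embed without failure
  expect_silent(embed_2d(rbind(X, X[1:3, ]), seed = 2, perplexity = 8,
                         n_iter = 50))
  expect_error(embed_2d(X[1:10, ], seed = 1, perplexity = 10),
               class = "gaitwin_validation_error")
})
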