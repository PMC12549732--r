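sep_data <- function(n = 60, seed = 19) {
  withr::with_seed(seed, {
    y <- factor(rep(c("low", "high"), c(n * 2 / 3, n / 3)),
                levels = c("low", "high"))
    X <- data.frame(f1 = ifelse(y == "high", 5, 0) + rnorm(n, 0, 0.3),
                    f2 = rnorm(n), f3 = rnorm(n))
    list(X = X, y = y)
  })
}

test_that("classifier metrics follow their closed forms on canonical matrices", {
  r <- evaluate_classifier(2, 2, 0, 8)
  expect_equal(round(r$Acc, 2), 0.83)
  expect_equal(round(r$BA, 2), 0.90)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1.0)
  expect_equal(round(r$F1, 2), 0.67)
  expect_equal(round(r$MCC, 2), 0.63)

  r0 <- evaluate_classifier(0, 0, 2, 10)
  expect_equal(c(r0$precision, r0$recall, r0$F1, r0$MCC), c(0, 0, 0, 0))

  r2 <- evaluate_classifier(1, 2, 1, 8)
  expect_equal(round(r2$BA, 2), 0.65)
  expect_equal(round(r2$F1, 2), 0.40)
  expect_equal(round(r2$MCC, 2), 0.26)
  expect_error(evaluate_classifier(-1, 0, 0, 5),
               class = "gaitwin_validation_error")
})

test_that("MCC stays within [-1,1] and identities hold on random matrices", {
  set.seed(23)
  for (i in 1:40) {
    cm <- as.vector(stats::rmultinom(1, size = sample(5:60, 1), prob = runif(4)))
    r <- evaluate_classifier(cm[1], cm[2], cm[3], cm[4])
    expect_gte(r$MCC, -1); expect_lte(r$MCC, 1)
    expect_equal(r$BA, (r$recall + ifelse(cm[4] + cm[2] > 0,
                                          cm[4] / (cm[4] + cm[2]), 0)) / 2)
    if (r$precision + r$recall > 0)
      expect_equal(r$F1, 2 * r$precision * r$recall / (r$precision + r$recall))
  }
})

test_that("rank AUC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + 1.2 * y
    expect_equal(auc_rank(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(auc_rank(1:3, c(TRUE, FALSE)),
               class = "gaitwin_validation_error")
})

test_that("confusion matrices are reconstructed uniquely from printed metrics", {
  expect_equal(confusion_from_metrics(12, 2, 0.83, 0.50, 1.0),
               c(TP = 2, FP = 2, FN = 0, TN = 8))
  expect_equal(confusion_from_metrics(12, 2, 0.92, 0.67, 1.0),
               c(TP = 2, FP = 1, FN = 0, TN = 9))
  expect_equal(confusion_from_metrics(12, 2, 0.75, 0.33, 0.50),
               c(TP = 1, FP = 2, FN = 1, TN = 8))
  expect_error(confusion_from_metrics(12, 2, 0.99, 0.10, 0.10),
               class = "gaitwin_no_solution_error")
  expect_error(confusion_from_metrics(200, 100, 0.5, 0.5, 0.5),
               class = "gaitwin_ambiguous_solution_error")
  expect_error(confusion_from_metrics(12, 2, 1.2, 0.5, 0.5),
               class = "gaitwin_validation_error")
})

test_that("perfectly separable features yield full recall on the held-out set", {
  d <- sep_data()
  for (mod in c("logreg", "rf")) {
    r <- train_and_evaluate(d$X, d$y, model = mod, n_iter = 5, seed = 31)
    expect_equal(r$recall, 1.0)
    expect_gte(r$BA, 0.95)
  }
})

test_that("training is deterministic given the seed", {
  d <- sep_data()
  r1 <- train_and_evaluate(d$X, d$y, model = "xgb", n_iter = 4, seed = 7)
  r2 <- train_and_evaluate(d$X, d$y, model = "xgb", n_iter = 4, seed = 7)
  expect_identical(r1[c("TP", "FP", "FN", "TN", "AUC", "best_params")],
                   r2[c("TP", "FP", "FN", "TN", "AUC", "best_params")])
})

test_that("shuffled labels stay near chance (no leakage through preprocessing)", {
  d <- sep_data(n = 48)
  bas <- vapply(1:20, function(s) {
    y_perm <- withr::with_seed(1000 + s, sample(d$y))
    train_and_evaluate(d$X, y_perm, model = "logreg", n_iter = 2,
                       seed = s)$BA
  }, numeric(1))
  expect_gte(mean(bas), 0.2)
  expect_lte(mean(bas), 0.8)
  expect_true(all(bas >= 0 & bas <= 1))
})

test_that("corrupting the test partition does not change what was learned", {
  d <- sep_data()
  r <- train_and_evaluate(d$X, d$y, model = "logreg", n_iter = 4, seed = 11)
  X2 <- d$X
  X2[r$test_idx, ] <- X2[r$test_idx, ] * 100 + 7  # corrupt held-out rows only
  r2 <- train_and_evaluate(X2, d$y, model = "logreg", n_iter = 4, seed = 11)
  expect_identical(r$best_params, r2$best_params)
  expect_equal(r$cv_ba, r2$cv_ba, tolerance = 1e-12)
  expect_identical(r$scaling$scale$min, r2$scaling$scale$min)
})

test_that("SMOTE augments training only; the test partition keeps its size", {
  d <- sep_data(n = 60)
  r <- train_and_evaluate(d$X, d$y, model = "rf", n_iter = 3,
                          imbalance = "smote", seed = 13)
  expect_equal(nrow(r$X_test), length(r$test_idx))
  expect_equal(length(r$y_test), length(r$test_idx))
  expect_equal(r$TP + r$FP + r$FN + r$TN, length(r$test_idx))
})

test_that("permutation attribution ranks the informative feature first", {
  d <- sep_data(n = 90)
  r <- train_and_evaluate(d$X, d$y, model = "rf", n_iter = 3, seed = 17)
  fa <- feature_attribution(r, repeats = 15, seed = 3)
  expect_equal(fa$feature[1], "f1")
  noise_imp <- fa$importance[fa$feature %in% c("f2", "f3")]
  expect_true(all(abs(noise_imp) < 0.15))
  fa2 <- feature_attribution(r, repeats = 15, seed = 3)
  expect_identical(fa, fa2)
  # exact additive attributions can be plugged in
  fa3 <- feature_attribution(r, exact_fun = function(fit, X)
    matrix(rep(c(3, 1, 0), each = nrow(X)), ncol = 3))
  expect_equal(fa3$importance, c(3, 1, 0))
})

test_that("feature tables exclude the label-defining variables by construction", {
  fx <- fixture_dir()
  co <- read_cohort_csv(file.path(fx, "cohort.csv"))
  m <- cohort_metrics(co, gait_params(duration_s = 20), master_seed = 101,
                      trials = NULL)
  ft <- build_feature_table(m)
  expect_false(any(c("ga_weeks", "bw_g") %in% names(ft$X)))
  expect_true(all(vapply(ft$X, is.numeric, logical(1))))
  expect_equal(levels(ft$y), c("low", "high"))
})
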