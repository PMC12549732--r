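#' Rank-based AUC
#'
#' Mann-Whitney statistic: probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param truth Logical/0-1 vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`; `NA` when a class is absent.
#' @export
auc_rank <- function(scores, truth) {
  if (length(scores) != length(truth))
    abort_gw("score vector length mismatch", "gaitwin_validation_error")
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Evaluate a binary classifier from its confusion matrix
#'
#' Computes accuracy, balanced accuracy, precision/recall/F1 of the
#' positive class, Matthews correlation coefficient and (when a score
#' vector is supplied) the rank-based AUC. Degenerate denominators follow
#' the zero convention: precision/recall/F1 are 0 when undefined, MCC is
#' 0 when any marginal is 0.
#'
#' @param TP,FP,FN,TN Confusion-matrix counts (positive class = first).
#' @param scores Optional test-set score vector for AUC.
#' @param truth Optional logical vector matching `scores` (positive class
#'   `TRUE`); must contain `TP + FN` positives and `FP + TN` negatives.
#' @param model Model name carried in the report.
#' @return Object of class `classifier_report`.
#' @export
evaluate_classifier <- function(TP, FP, FN, TN, scores = NULL, truth = NULL,
                                model = "") {
  counts <- c(TP, FP, FN, TN)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 1)
    abort_gw("confusion counts must be non-negative integers with n >= 1",
             "gaitwin_validation_error")
  n <- TP + FP + FN + TN
  acc <- (TP + TN) / n
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  spec <- if (TN + FP > 0) TN / (TN + FP) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  ba <- (rec + spec) / 2
  denom <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth))
      abort_gw("truth labels required with scores", "gaitwin_validation_error")
    if (length(scores) != length(truth) ||
        sum(truth) != TP + FN || sum(!truth) != FP + TN)
      abort_gw("score vector inconsistent with confusion matrix",
               "gaitwin_validation_error")
    auc <- auc_rank(scores, truth)
  }
  structure(list(model = model, TP = TP, FP = FP, FN = FN, TN = TN,
                 Acc = acc, BA = ba, precision = prec, recall = rec,
                 F1 = f1, AUC = auc, MCC = mcc),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier report [%s]\n", x$model))
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  Acc=%.2f BA=%.2f P=%.2f R=%.2f F1=%.2f AUC=%s MCC=%.2f\n",
              x$Acc, x$BA, x$precision, x$recall, x$F1,
              ifelse(is.na(x$AUC), "NA", sprintf("%.2f", x$AUC)), x$MCC))
  invisible(x)
}

#' Reconstruct the confusion matrix from printed metrics
#'
#' Exhaustive search over all integer confusion matrices with `TP + FN =
#' n_pos` and total `n_test`, returning the unique matrix whose accuracy,
#' precision and recall round (2 d.p., half-up) to the printed values.
#'
#' @param n_test Test-set size.
#' @param n_pos Number of positives in the test set.
#' @param acc,precision,recall Printed metric values (2 d.p.).
#' @return Named vector `c(TP, FP, FN, TN)`.
#' @export
confusion_from_metrics <- function(n_test, n_pos, acc, precision, recall) {
  if (any(c(acc, precision, recall) < 0) || any(c(acc, precision, recall) > 1))
    abort_gw("metrics must lie in [0, 1]", "gaitwin_validation_error")
  sols <- list()
  for (tp in 0:n_pos) {
    fn <- n_pos - tp
    for (fp in 0:(n_test - n_pos)) {
      tn <- n_test - n_pos - fp
      a <- (tp + tn) / n_test
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (round_half_up(a) == round_half_up(acc) &&
          round_half_up(p) == round_half_up(precision) &&
          round_half_up(r) == round_half_up(recall))
        sols[[length(sols) + 1L]] <- c(TP = tp, FP = fp, FN = fn, TN = tn)
    }
  }
  if (length(sols) == 0L)
    abort_gw("no integer confusion matrix matches the printed metrics",
             "gaitwin_no_solution_error")
  if (length(sols) > 1L)
    abort_gw(sprintf("ambiguous: %d matrices match", length(sols)),
             "gaitwin_ambiguous_solution_error")
  sols[[1]]
}

# ---- learners -------------------------------------------------------------

#' Pluggable learner specification
#'
#' Returns a learner adapter: a random hyper-parameter sampler, a fit
#' function (accepting per-class weights) and a positive-class score
#' function. Available learners: `"logreg"` (elastic-net logistic
#' regression), `"svm_linear"`, `"dtree"`, `"rf"`, `"xgb"`.
#'
#' @param name Learner name.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("logreg", "svm_linear", "dtree", "rf", "xgb")) {
  name <- match.arg(name)
  spec <- switch(name,
    logreg = list(
      sample = function() list(alpha = runif(1),
                               lambda = 10^runif(1, -4, 0)),
      fit = function(X, y, par, cw, seed) {
        w <- cw[as.character(y)]
        glmnet::glmnet(as.matrix(X), y, family = "binomial",
                       alpha = par$alpha, lambda = par$lambda, weights = w)
      },
      score = function(fit, X)
        as.numeric(predict(fit, as.matrix(X), type = "response"))),
    svm_linear = list(
      sample = function() list(cost = 10^runif(1, -2, 2)),
      fit = function(X, y, par, cw, seed)
        e1071::svm(as.matrix(X), y, kernel = "linear", cost = par$cost,
                   class.weights = cw, scale = FALSE),
      score = function(fit, X) {
        dv <- attr(predict(fit, as.matrix(X), decision.values = TRUE),
                   "decision.values")
        s <- as.numeric(dv)
        # orient decision values towards the positive ("high") class
        if (!grepl("^high", colnames(dv)[1])) s <- -s
        s
      }),
    dtree = list(
      sample = function() list(cp = 10^runif(1, -4, -1),
                               maxdepth = sample(2:10, 1),
                               minsplit = sample(2:10, 1)),
      fit = function(X, y, par, cw, seed) {
        df <- data.frame(X, .y = y)
        rpart::rpart(.y ~ ., df, weights = cw[as.character(y)],
                     control = rpart::rpart.control(
                       cp = par$cp, maxdepth = par$maxdepth,
                       minsplit = par$minsplit))
      },
      score = function(fit, X)
        predict(fit, data.frame(X), type = "prob")[, "high"]),
    rf = list(
      sample = function() list(mtry = sample(2:12, 1),
                               nodesize = sample(1:5, 1), ntree = 300L),
      fit = function(X, y, par, cw, seed)
        randomForest::randomForest(
          as.matrix(X), y, ntree = par$ntree,
          mtry = min(par$mtry, ncol(X)), nodesize = par$nodesize,
          classwt = cw[levels(y)]),
      score = function(fit, X)
        predict(fit, as.matrix(X), type = "prob")[, "high"]),
    xgb = list(
      sample = function() list(eta = runif(1, 0.01, 0.3),
                               max_depth = sample(2:6, 1),
                               nrounds = sample(50:300, 1),
                               subsample = runif(1, 0.6, 1)),
      fit = function(X, y, par, cw, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                       label = as.integer(y == "high"))
        xgboost::xgb.train(
          params = xgboost::xgb.params(
            objective = "binary:logistic", learning_rate = par$eta,
            max_depth = par$max_depth, subsample = par$subsample,
            scale_pos_weight = cw[["high"]] / cw[["low"]],
            nthread = 1, seed = seed %% .Machine$integer.max),
          data = dtrain, nrounds = par$nrounds, verbose = 0)
      },
      score = function(fit, X)
        predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))))
  structure(c(spec, list(name = name)), class = "model_spec")
}

# stratified fold assignment; reduces folds with a warning when the rarer
# class cannot cover them
stratified_folds <- function(y, k, seed) {
  k_eff <- min(k, min(table(y)))
  if (k_eff < k) warning(sprintf("reducing CV folds to %d", k_eff))
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k_eff), length(idx))
    }
    fold
  })
}

stratified_split <- function(y, train_frac, seed) {
  with_seed(seed, {
    train <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- round(train_frac * length(idx))
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })
}

#' Build a feature table from the cohort metrics
#'
#' Encodes the categorical clinical features numerically (`sex`: F = 0,
#' M = 1; `twin`: 0/1), keeps only [metric_schema()] columns (so
#' gestational age and birth weight can never leak in) and extracts the
#' risk label.
#'
#' @param metrics Metrics `data.frame` from [cohort_metrics()].
#' @return List with `X` (numeric data.frame), `y` (factor low/high,
#'   positive class `"high"`), `child_id`.
#' @export
build_feature_table <- function(metrics) {
  X <- metrics[intersect(metric_schema(), names(metrics))]
  if ("sex" %in% names(X)) X$sex <- as.numeric(X$sex == "M")
  if ("twin" %in% names(X)) X$twin <- as.numeric(as.logical(X$twin))
  X[] <- lapply(X, as.numeric)
  # drop features that are entirely missing (e.g. skipped normalisation)
  keep <- vapply(X, function(c) !all(is.na(c)), logical(1))
  list(X = X[keep], y = factor(metrics$risk, levels = c("low", "high")),
       child_id = metrics$child_id)
}

#' Train and evaluate a classifier with randomized search
#'
#' Stratified 75/25 train/test split; imputation and min-max scaling are
#' fitted on the training partition only and applied to the test
#' partition. Hyper-parameters are drawn at random and scored by balanced
#' accuracy under stratified k-fold cross-validation on the training set,
#' with class weights inversely proportional to class frequencies (or
#' SMOTE applied to the training folds only). The winner is refitted on
#' the full training set and reported on the untouched test set.
#'
#' @param X Numeric feature `data.frame` (unscaled; may contain `NA`).
#' @param y Factor with levels `c("low", "high")`.
#' @param model A learner name or [model_spec()].
#' @param split Training fraction.
#' @param cv_folds CV folds for the search.
#' @param n_iter Randomized-search draws.
#' @param imbalance `"weights"` or `"smote"`.
#' @param seed Integer seed controlling split, folds, search and fits.
#' @return A `classifier_report` with extra fields `best_params`, `cv_ba`,
#'   `fit` (refitted model), `spec`, `test_idx`, `X_test`, `y_test`,
#'   `scaling`.
#' @export
train_and_evaluate <- function(X, y, model = "xgb", split = 0.75,
                               cv_folds = 5L, n_iter = 20L,
                               imbalance = c("weights", "smote"),
                               seed = 1L) {
  imbalance <- match.arg(imbalance)
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  if (min(table(y)) < 2L)
    abort_gw("need >= 2 examples per class", "gaitwin_validation_error")
  is_train <- stratified_split(y, split, derive_seed(seed, "split"))
  prep <- fit_preprocessor(X[is_train, , drop = FALSE])
  X_tr <- prep$transform(X[is_train, , drop = FALSE])
  X_te <- prep$transform(X[!is_train, , drop = FALSE])
  y_tr <- droplevels(y[is_train]); y_te <- y[!is_train]

  params <- with_seed(derive_seed(seed, "search"),
                      lapply(seq_len(n_iter), function(i) spec$sample()))
  fold <- stratified_folds(y_tr, cv_folds, derive_seed(seed, "folds"))
  cv_ba <- vapply(seq_along(params), function(pi) {
    bas <- vapply(sort(unique(fold)), function(f) {
      tr <- fold != f
      cv_score(spec, params[[pi]], X_tr[tr, , drop = FALSE], y_tr[tr],
               X_tr[!tr, , drop = FALSE], y_tr[!tr], imbalance,
               derive_seed(seed, paste0("cv/", pi, "/", f)))
    }, numeric(1))
    mean(bas, na.rm = TRUE)
  }, numeric(1))
  best <- params[[which.max(cv_ba)]]

  fitted <- fit_with_imbalance(spec, best, X_tr, y_tr, imbalance,
                               derive_seed(seed, "refit"))
  scores <- spec$score(fitted, X_te)
  pred_pos <- if (all(scores >= 0 & scores <= 1)) scores >= 0.5 else scores >= 0
  truth_pos <- y_te == "high"
  rep <- evaluate_classifier(sum(pred_pos & truth_pos),
                             sum(pred_pos & !truth_pos),
                             sum(!pred_pos & truth_pos),
                             sum(!pred_pos & !truth_pos),
                             scores = scores, truth = truth_pos,
                             model = spec$name)
  rep$best_params <- best
  rep$cv_ba <- max(cv_ba)
  rep$fit <- fitted
  rep$spec <- spec
  rep$test_idx <- which(!is_train)
  rep$X_test <- X_te
  rep$y_test <- y_te
  rep$scaling <- prep$params
  rep
}

# impute (train means) + min-max (train range), applied to any partition
fit_preprocessor <- function(X_train) {
  mu <- vapply(X_train, function(c) mean(c, na.rm = TRUE), numeric(1))
  filled <- X_train
  for (j in seq_along(filled)) filled[[j]][is.na(filled[[j]])] <- mu[[j]]
  sc <- suppressWarnings(minmax_scale(filled))
  list(params = list(impute_mean = mu, scale = sc$params),
       transform = function(X) {
         for (j in seq_along(X)) X[[j]][is.na(X[[j]])] <- mu[[j]]
         minmax_scale(X, sc$params)$scaled
       })
}

cv_score <- function(spec, par, X_tr, y_tr, X_va, y_va, imbalance, seed) {
  if (length(unique(y_va)) < 2L || length(unique(y_tr)) < 2L) return(NA_real_)
  fit <- tryCatch(
    fit_with_imbalance(spec, par, X_tr, y_tr, imbalance, seed),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  s <- spec$score(fit, X_va)
  pos <- if (all(s >= 0 & s <= 1)) s >= 0.5 else s >= 0
  truth <- y_va == "high"
  rec <- if (sum(truth)) sum(pos & truth) / sum(truth) else 0
  spc <- if (sum(!truth)) sum(!pos & !truth) / sum(!truth) else 0
  (rec + spc) / 2
}

fit_with_imbalance <- function(spec, par, X, y, imbalance, seed) {
  if (imbalance == "smote" && length(unique(y)) == 2L &&
      min(table(y)) > 2L) {
    k <- min(5L, min(table(y)) - 1L)
    sm <- smote_oversample(as.matrix(X), as.character(y), k_neighbors = k,
                           seed = seed)
    X <- as.data.frame(sm$X)
    y <- factor(sm$y, levels = levels(y))
    cw <- c(low = 1, high = 1)
  } else {
    cw <- class_weights(y)
    cw <- cw[c("low", "high")]
    names(cw) <- c("low", "high")
  }
  with_seed(seed, spec$fit(X, y, par, cw, seed))
}

#' Permutation feature attribution
#'
#' Mean balanced-accuracy drop on the test set when one feature is
#' permuted, averaged over repeated shuffles, with a sign taken from the
#' correlation between the feature and the model score. Exact additive
#' attributions can be plugged in via `exact_fun` when the learner
#' provides them.
#'
#' @param report A `classifier_report` from [train_and_evaluate()].
#' @param repeats Number of permutations per feature.
#' @param seed Integer seed.
#' @param exact_fun Optional `function(fit, X_test)` returning an
#'   n x p matrix of exact additive attributions; when supplied, its mean
#'   absolute value per feature is reported instead of permutation drops.
#' @return `data.frame` `feature`, `importance`, `direction`, sorted by
#'   importance.
#' @export
feature_attribution <- function(report, repeats = 30L, seed = 1L,
                                exact_fun = NULL) {
  spec <- report$spec; fit <- report$fit
  X <- report$X_test; y <- report$y_test
  truth <- y == "high"
  score0 <- spec$score(fit, X)
  if (!is.null(exact_fun)) {
    phi <- exact_fun(fit, X)
    imp <- colMeans(abs(phi))
  } else {
    ba_of <- function(s) {
      pos <- if (all(s >= 0 & s <= 1)) s >= 0.5 else s >= 0
      rec <- if (sum(truth)) sum(pos & truth) / sum(truth) else 0
      spc <- if (sum(!truth)) sum(!pos & !truth) / sum(!truth) else 0
      (rec + spc) / 2
    }
    base <- ba_of(score0)
    imp <- vapply(seq_along(X), function(j) {
      drops <- vapply(seq_len(repeats), function(r) {
        Xp <- X
        Xp[[j]] <- with_seed(derive_seed(seed, paste0("perm/", j, "/", r)),
                             sample(Xp[[j]]))
        base - ba_of(spec$score(fit, Xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  }
  dir <- vapply(seq_along(X), function(j) {
    if (sd(X[[j]]) == 0 || sd(score0) == 0) return(0)
    sign(cor(X[[j]], score0))
  }, numeric(1))
  out <- data.frame(feature = names(X), importance = imp, direction = dir,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
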