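#' Impute missing values by column mean or median
#'
#' Each missing cell is replaced by the column statistic computed on the
#' observed values of that column only. The imputation mask is retained
#' as the `imputed` attribute.
#'
#' @param table Numeric `data.frame` or matrix.
#' @param strategy `"mean"` or `"median"`.
#' @return The imputed table with attribute `imputed` (logical mask).
#' @export
impute <- function(table, strategy = c("mean", "median")) {
  strategy <- match.arg(strategy)
  stat <- if (strategy == "mean") mean else median
  df <- as.data.frame(table)
  mask <- is.na(df)
  for (j in seq_along(df)) {
    miss <- is.na(df[[j]])
    if (!any(miss)) next
    if (all(miss))
      abort_gw(sprintf("column '%s' is entirely missing", names(df)[j]),
               "gaitwin_validation_error")
    df[[j]][miss] <- stat(df[[j]][!miss])
  }
  attr(df, "imputed") <- mask
  df
}

#' Min-max scaling to [0, 1]
#'
#' `(x - min) / (max - min)` per feature. A constant feature maps to zero
#' with a warning. The returned parameters allow exact inversion and
#' application to new data.
#'
#' @param table Numeric `data.frame`/matrix with no missing values.
#' @param params Optional previously fitted parameters (applies them
#'   instead of fitting; values outside the fitted range map outside
#'   `[0, 1]`, as when scaling a held-out test set).
#' @return List with `scaled` (data.frame) and `params` (per-feature
#'   `min`/`max`).
#' @export
minmax_scale <- function(table, params = NULL) {
  df <- as.data.frame(table)
  if (any(vapply(df, function(c) any(is.na(c)), logical(1))))
    abort_gw("missing values present: impute first",
             "gaitwin_validation_error")
  if (is.null(params)) {
    params <- list(min = vapply(df, min, numeric(1)),
                   max = vapply(df, max, numeric(1)))
    if (any(params$max == params$min))
      warning("constant feature(s) scaled to zero: ",
              paste(names(df)[params$max == params$min], collapse = ", "))
  }
  for (j in seq_along(df)) {
    rng <- params$max[[j]] - params$min[[j]]
    df[[j]] <- if (rng == 0) rep(0, nrow(df)) else
      (df[[j]] - params$min[[j]]) / rng
  }
  list(scaled = df, params = params)
}

#' Invert min-max scaling
#' @param scaled Scaled table.
#' @param params Parameters from [minmax_scale()].
#' @return The table on the original scale.
#' @export
minmax_unscale <- function(scaled, params) {
  df <- as.data.frame(scaled)
  for (j in seq_along(df)) {
    rng <- params$max[[j]] - params$min[[j]]
    df[[j]] <- if (rng == 0) rep(params$min[[j]], nrow(df)) else
      df[[j]] * rng + params$min[[j]]
  }
  df
}

#' Class weights inversely proportional to class frequencies
#'
#' `w_c = n_total / (n_classes * n_c)`, so that
#' `sum_c w_c * n_c = n_total` and balanced classes get weight 1.
#'
#' @param labels Factor or character vector with exactly two classes
#'   present.
#' @return Named numeric vector of weights.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  tab <- tab[tab > 0]
  if (length(tab) < 2L)
    abort_gw("need both classes present", "gaitwin_validation_error")
  n <- sum(tab)
  w <- n / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

#' SMOTE oversampling of the minority class
#'
#' Brings the minority class up to the majority count by interpolation:
#' each synthetic point is `x_i + u * (x_nn - x_i)` with `u ~ U(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest minority neighbours of a
#' randomly chosen minority point `x_i`. Deterministic given the seed.
#'
#' @param X Numeric matrix/data.frame of features.
#' @param y Labels (two classes).
#' @param k_neighbors Number of minority nearest neighbours.
#' @param seed Integer seed.
#' @return List with `X` (original rows followed by synthetic rows), `y`,
#'   and `synthetic` (logical marker per row).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- sort(table(y))
  minority <- names(tab)[1]
  n_min <- tab[[1]]; n_maj <- tab[[length(tab)]]
  if (n_min <= k_neighbors)
    abort_gw(sprintf(paste0("minority class has %d samples; needs more than ",
                            "k_neighbors = %d (reduce k_neighbors)"),
                     n_min, k_neighbors),
             "gaitwin_validation_error")
  need <- n_maj - n_min
  if (need == 0L)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  idx_min <- which(y == minority)
  Xm <- X[idx_min, , drop = FALSE]
  d <- as.matrix(dist(Xm))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(d[i, ])[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base_i <- sample(seq_len(n_min), need, replace = TRUE)
    nn_j <- vapply(base_i, function(i) nn[i, sample(k_neighbors, 1L)],
                   numeric(1))
    u <- runif(need)
    Xm[base_i, , drop = FALSE] +
      u * (Xm[nn_j, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  list(X = rbind(X, synth),
       y = c(y, rep(minority, need)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
}
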