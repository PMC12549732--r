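#' Two-dimensional t-SNE embedding for visual quality control
#'
#' Exact (non-approximated) t-SNE: per-point Gaussian bandwidths are tuned
#' by binary search to the target perplexity, the symmetrised affinities
#' are embedded by gradient descent with momentum and early exaggeration.
#' Suitable for the cohort sizes this package targets (tens to a few
#' hundred points); the embedding is for visual QC only and is reported
#' together with a neighbourhood-preservation score (fraction of each
#' point's 5 nearest neighbours preserved in the plane).
#'
#' @param X Numeric matrix/data.frame (rows = children).
#' @param seed Integer seed (initialisation and gradient noise).
#' @param perplexity Target perplexity; `n` must be at least
#'   `3 * perplexity`.
#' @param n_iter Gradient-descent iterations.
#' @return List with `Y` (n x 2 coordinates) and `knn_preservation`
#'   (scalar in `[0, 1]`).
#' @export
embed_2d <- function(X, seed = 1L, perplexity = 10, n_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3 * perplexity)
    abort_gw("n must be at least 3 * perplexity",
             "gaitwin_validation_error")
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    mom <- if (it <= 250) 0.5 else 0.8
    dy2 <- as.matrix(dist(Y))^2
    Q_num <- 1 / (1 + dy2); diag(Q_num) <- 0
    Q <- pmax(Q_num / sum(Q_num), 1e-12)
    L <- (ex * P - Q) * Q_num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  list(Y = Y, knn_preservation = knn_preservation(X, Y, k = 5L))
}

# Fraction of each point's k nearest high-dimensional neighbours that are
# also among its k nearest neighbours in the embedding.
knn_preservation <- function(X, Y, k = 5L) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  dx <- as.matrix(dist(X)); dy <- as.matrix(dist(Y))
  diag(dx) <- Inf; diag(dy) <- Inf
  mean(vapply(seq_len(n), function(i) {
    length(intersect(order(dx[i, ])[1:k], order(dy[i, ])[1:k])) / k
  }, numeric(1)))
}
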