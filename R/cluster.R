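#' Repeated k-means with matched clusters, feature importance and KDE
#'
#' Runs k-means (`k = 2`) `runs` times with seeds derived from the master
#' seed, matches cluster labels across runs by centroid proximity to the
#' first run, forms a consensus assignment by majority vote, and scores
#' per-feature importance as the absolute difference of the two (scaled)
#' centroids, summarised as mean and SD over runs. Gaussian kernel
#' density estimates (Silverman's rule-of-thumb bandwidth) of the top
#' features are returned per consensus cluster.
#'
#' @param X Scaled numeric matrix/data.frame (features in `[0, 1]`).
#' @param k Number of clusters (the analysis uses 2).
#' @param runs Number of repeated runs.
#' @param seed Master seed.
#' @param kde_top Number of top-importance features to summarise with KDE.
#' @return Object of class `cluster_result`: `assignments` (runs x n
#'   matrix), `consensus`, `centroids` (list per run), `importance`
#'   (data.frame feature/mean/sd, sorted), `kde` (named list of per-cluster
#'   densities).
#' @export
kmeans_repeated <- function(X, k = 2L, runs = 30L, seed = 1L, kde_top = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) abort_gw("fewer points than clusters", "gaitwin_validation_error")
  fits <- lapply(seq_len(runs), function(r) {
    with_seed(derive_seed(seed, paste0("kmeans/", r)),
              kmeans(X, centers = k, nstart = 1L, iter.max = 100L))
  })
  ref <- fits[[1]]$centers
  assignments <- matrix(NA_integer_, runs, n)
  centroids <- vector("list", runs)
  imp <- matrix(NA_real_, runs, ncol(X))
  for (r in seq_len(runs)) {
    f <- fits[[r]]
    # match this run's clusters to run 1 by centroid distance
    perm <- if (k == 2L) {
      d_id <- sum((f$centers[1, ] - ref[1, ])^2) + sum((f$centers[2, ] - ref[2, ])^2)
      d_sw <- sum((f$centers[1, ] - ref[2, ])^2) + sum((f$centers[2, ] - ref[1, ])^2)
      if (d_id <= d_sw) 1:2 else 2:1
    } else seq_len(k)
    assignments[r, ] <- perm[f$cluster]
    centroids[[r]] <- f$centers[order(perm), , drop = FALSE]
    if (k == 2L)
      imp[r, ] <- abs(centroids[[r]][1, ] - centroids[[r]][2, ])
  }
  consensus <- apply(assignments, 2, function(col)
    as.integer(names(which.max(table(col)))))
  importance <- data.frame(
    feature = colnames(X) %||% paste0("f", seq_len(ncol(X))),
    mean = colMeans(imp), sd = apply(imp, 2, sd),
    stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean), ]
  rownames(importance) <- NULL
  top <- head(importance$feature, kde_top)
  kde <- lapply(stats::setNames(top, top), function(f) {
    j <- match(f, colnames(X))
    lapply(stats::setNames(seq_len(k), paste0("cluster", seq_len(k))),
           function(cl) {
             v <- X[consensus == cl, j]
             if (length(v) < 2 || sd(v) == 0) NULL else
               density(v, bw = "nrd0", kernel = "gaussian")[c("x", "y")]
           })
  })
  structure(list(assignments = assignments, consensus = consensus,
                 centroids = centroids, importance = importance, kde = kde,
                 k = k, runs = runs),
            class = "cluster_result")
}

#' Cluster composition with respect to a label
#'
#' For each consensus cluster, the count and fraction of each label value
#' (e.g. the share of high-risk children per cluster).
#'
#' @param result A `cluster_result`.
#' @param labels Vector of per-child labels.
#' @return `data.frame` with `cluster`, `label`, `n`, `fraction`.
#' @export
cluster_composition <- function(result, labels) {
  tab <- table(cluster = result$consensus, label = labels)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("cluster", "label", "n")
  tot <- rowSums(tab)
  out$fraction <- out$n / tot[out$cluster]
  out
}
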