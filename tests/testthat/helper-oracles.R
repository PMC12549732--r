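# Independent brute-force references used to validate the optimized kernels.

# Sample entropy by direct enumeration of template pairs (plain R loops).
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# RQA by materialising the full recurrence matrix and scanning diagonals.
rqa_bruteforce <- function(x, dim, delay, radius, theiler, lmin) {
  ne <- length(x) - (dim - 1) * delay
  emb <- sapply(seq_len(dim), function(k) x[(1:ne) + (k - 1) * delay])
  D <- as.matrix(dist(emb))
  R <- D <= radius
  rec <- 0; npairs <- 0; pts <- 0; nlines <- 0; sumlen <- 0
  for (d in (theiler + 1):(ne - 1)) {
    diag_vals <- R[cbind(1:(ne - d), (1 + d):ne)]
    npairs <- npairs + length(diag_vals)
    rec <- rec + sum(diag_vals)
    runs <- rle(diag_vals)
    lens <- runs$lengths[runs$values & runs$lengths >= lmin]
    pts <- pts + sum(lens)
    nlines <- nlines + length(lens)
    sumlen <- sumlen + sum(lens)
  }
  c(RR = rec / npairs,
    DET = if (rec > 0) pts / rec else 0,
    AvgL = if (nlines > 0) sumlen / nlines else NA_real_)
}

# A trial pair (left/right stride series) built directly from event times,
# bypassing signal detection, for hand-computed temporal examples.
stride_series_from_times <- function(leg, hs, to, ms = NULL) {
  if (is.null(ms)) {
    n <- min(length(to), length(hs) - 1L)
    ms <- (to[seq_len(n)] + hs[-1L][seq_len(n)]) / 2
  }
  structure(list(leg = leg, heel_strikes = hs, toe_offs = to,
                 mid_swings = ms), class = "stride_series")
}

# Shared fixture directory (built once per test run).
fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "gaitwin-fixtures")
      if (!file.exists(file.path(dir, "cohort.csv")))
        make_fixtures(dir, seed = 101L)
    }
    dir
  }
})
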