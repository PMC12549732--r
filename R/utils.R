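#' @useDynLib gaitwin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd density kmeans dist predict rnorm runif
#'   median cor setNames
#' @importFrom utils write.csv read.csv head modifyList
NULL

# MD5 of a string via base tools::md5sum (content written with no trailing
# newline so the digest is a pure function of the bytes).
md5_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeChar(x, f, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(f))
}

#' Derive a stable child seed from a master seed and a string key
#'
#' First 7 hex digits of the MD5 of `"<seed>/<key>"`, i.e. an integer in
#' `[0, 16^7)`, always below 2^31. Used for all per-child / per-run RNG
#' streams so any sub-computation can be reproduced in isolation.
#'
#' @param master_seed Integer master seed.
#' @param key String naming the stream (e.g. `"trial/child-001"`).
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  h <- md5_string(paste0(as.integer(master_seed), "/", key))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

# Hash of an arbitrary (JSON-serializable) configuration object.
config_hash <- function(cfg) {
  md5_string(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"))
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

abort_gw <- function(msg, class, ...) {
  stop(structure(class = c(class, "gaitwin_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
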