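#' @useDynLib semloc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft var sd median quantile rnorm runif rpois rbinom
#'   setNames complete.cases cor cor.test t.test pt
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Great-circle (haversine) distance in meters between (lat1,lon1) and
# (lat2,lon2) on the WGS-84 sphere, vectorised over either argument pair.
# Direct formula rather than geosphere::distHaversine: numerically
# identical (same 6378137 m radius; asserted in the tests) but without
# per-call input marshalling, which matters in the clustering inner loop.
dist_m <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * (pi / 180); p2 <- lat2 * (pi / 180)
  a <- sin((p2 - p1) / 2)^2 +
    cos(p1) * cos(p2) * sin((lon2 - lon1) * (pi / 360))^2
  2 * 6378137 * asin(pmin(1, sqrt(a)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never disturbs user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a child seed from a base seed and a stream label, staying within
# 32-bit integer range.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  s <- 0
  for (ch in utf8ToInt(key)) s <- (s * 131 + ch) %% 2147483563
  as.integer(s + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
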