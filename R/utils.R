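#' @importFrom data.table data.table as.data.table setkey setorder uniqueN .N
#' @importFrom stats rnorm runif rpois rbinom rgamma rlnorm cor sd quantile
#' @importFrom utils head read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib tractprev, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`%s` must be a single number", name)
  }
  invisible(x)
}

# Shoelace area of a closed ring (first row repeated last); positive for CCW.
ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

# Area-weighted centroid of a simple closed ring.
ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  cross <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cross) / 2
  cx <- sum((x[-n] + x[-1L]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1L]) * cross) / (6 * a)
  c(cx, cy)
}
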