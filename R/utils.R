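#' Evaluate an expression under a fixed, restorable RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that a given seed yields byte-identical output and the
#' caller's RNG stream is left untouched.
#'
#' @param seed integer seed (kept below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# derive a reproducible sub-seed from a base seed and a stage offset,
# staying inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587)
}

# circular distance between angles on a cycle of `period` degrees
circ_dist <- function(a, b, period = 360) {
  d <- abs((a - b) %% period)
  pmin(d, period - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative arc length of an ordered polyline
#' @param points n x 2 matrix of coordinates.
#' @return numeric vector of length n, starting at 0.
#' @keywords internal
arc_length <- function(points) {
  d <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(d))
}
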