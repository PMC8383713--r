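#' @importFrom stats fft median quantile rnorm runif sd mad wilcox.test approx rbinom
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic components of the package draw their randomness from one
#' master seed through this splitter, so sub-streams (e.g. the RR series and
#' the burst heights of a simulated recording) are independently
#' reproducible. The result is always a valid 32-bit R seed.
#'
#' @param seed master integer seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((abs(seed) * 7919 + stream * 104729 + 17) %% 2147483647)
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stop_arg("'%s' must be strictly positive", name)
  invisible(x)
}

# Local maxima of a numeric vector, plateau-aware: a plateau bounded by a
# strict rise and a strict fall counts once, at its (floored) midpoint.
# Endpoints never qualify.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  dd <- d[nz]
  turn <- which(dd[-length(dd)] == 1 & dd[-1] == -1)
  if (!length(turn)) return(integer(0))
  left <- nz[turn] + 1L
  right <- nz[turn + 1L]
  as.integer((left + right) %/% 2L)
}

find_local_minima <- function(x) find_local_maxima(-x)

# Greedy distance pruning: process peaks from highest to lowest (ties ->
# earlier first); a peak is kept only if no already-kept peak lies within
# min_dist samples. Returns a logical keep-mask aligned with `idx`.
prune_by_distance <- function(idx, heights, min_dist) {
  if (length(idx) <= 1L || min_dist <= 0) return(rep(TRUE, length(idx)))
  ord <- order(-heights, idx)
  keep <- rep(TRUE, length(idx))
  for (k in ord) {
    if (!keep[k]) next
    close_by <- which(abs(idx - idx[k]) < min_dist)
    keep[setdiff(close_by, k)] <- FALSE
  }
  keep
}
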