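# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition with different code paths than the package
# implementation (explicit walks instead of vectorized searches), so
# agreement is evidence, not tautology.

# Strict interior local maxima (oracle signals are continuous, no plateaus).
oracle_local_maxima <- function(x) {
  out <- integer(0)
  for (i in 2:(length(x) - 1L))
    if (x[i] > x[i - 1L] && x[i] > x[i + 1L]) out <- c(out, i)
  out
}

# Prominence by outward walk: on each side accumulate the running minimum
# until terrain higher than the peak (or the edge) stops the walk.
oracle_prominence <- function(x, i) {
  h <- x[i]
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    lmin <- min(lmin, x[j])
    j <- j - 1L
  }
  rmin <- h
  j <- i + 1L
  while (j <= length(x) && x[j] <= h) {
    rmin <- min(rmin, x[j])
    j <- j + 1L
  }
  h - max(lmin, rmin)
}

# Width at half prominence: walk out to the interpolated crossing of the
# evaluation height, bounded by the base minima.
oracle_width_ms <- function(x, i, prom, sample_rate = 1000) {
  eval_h <- x[i] - prom / 2
  h <- x[i]
  # locate base positions by re-walking
  lbase <- i
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < lmin) { lmin <- x[j]; lbase <- j }
    j <- j - 1L
  }
  rbase <- i
  rmin <- h
  j <- i + 1L
  while (j <= length(x) && x[j] <= h) {
    if (x[j] < rmin) { rmin <- x[j]; rbase <- j }
    j <- j + 1L
  }
  j <- i
  while (j > lbase && x[j] > eval_h) j <- j - 1L
  left <- j
  if (x[j] < eval_h) left <- j + (eval_h - x[j]) / (x[j + 1L] - x[j])
  j <- i
  while (j < rbase && x[j] > eval_h) j <- j + 1L
  right <- j
  if (x[j] < eval_h) right <- j - (eval_h - x[j]) / (x[j - 1L] - x[j])
  (right - left) * 1000 / sample_rate
}

# Full detector: height bounds, then the distance rule (re-implemented as an
# explicit keep-list scan), then prominence, then width.
oracle_detect <- function(x, params = peak_params(), sample_rate = 1000) {
  idx <- oracle_local_maxima(x)
  idx <- idx[x[idx] >= params$min_height & x[idx] <= params$max_height]
  if (length(idx) > 1L) {
    ord <- idx[order(-x[idx], idx)]
    kept <- integer(0)
    dist <- params$min_distance * sample_rate / 1000
    for (i in ord) if (!any(abs(kept - i) < dist)) kept <- c(kept, i)
    idx <- sort(kept)
  }
  prom <- vapply(idx, function(i) oracle_prominence(x, i), numeric(1))
  sel <- prom >= params$min_prominence
  idx <- idx[sel]
  prom <- prom[sel]
  wid <- vapply(seq_along(idx), function(k)
    oracle_width_ms(x, idx[k], prom[k], sample_rate), numeric(1))
  sel <- wid >= params$min_width
  data.frame(index = idx[sel], prominence = prom[sel], width_ms = wid[sel])
}

# Numeric area-integration oracle for the circular composite score.
oracle_composite <- function(profile, grid = 2e5) {
  bounds <- cumsum(c(0, profile$fraction))
  theta <- (seq_len(grid) - 0.5) / grid
  seg <- findInterval(theta, bounds, rightmost.closed = TRUE)
  mean(profile$value[seg])
}

# Mann-Whitney U for group x by explicit pair counting (ties half-weighted).
oracle_u_stat <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Smooth random test signal: low-pass noise plus a few burst-like bumps,
# amplitudes chosen to exercise every filter including the height cap.
random_msna_signal <- function(duration_s = 10, seed = 1, sample_rate = 1000) {
  withr::with_seed(seed, {
    n <- duration_s * sample_rate
    k <- 150
    base <- stats::filter(rnorm(n + k), rep(1 / k, k), sides = 1)[(k + 1):(n + k)]
    x <- 0.08 + as.numeric(base) * 0.3
    n_bump <- rpois(1, duration_s / 2) + 1L
    at <- sample.int(n, n_bump)
    hts <- runif(n_bump, 0.05, 1.0)
    wid <- runif(n_bump, 60, 250)
    for (b in seq_len(n_bump)) {
      rng <- max(1L, at[b] - 800L):min(n, at[b] + 800L)
      x[rng] <- x[rng] + hts[b] * exp(-((rng - at[b]) / wid[b])^2 / 2)
    }
    x
  })
}

# Composite-free matcher: closest distance from each event to a time grid.
match_within <- function(times, targets, tol_s) {
  vapply(times, function(t) any(abs(targets - t) <= tol_s), logical(1))
}
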