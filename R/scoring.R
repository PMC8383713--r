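#' Weights of the circular evidence profile
#'
#' Every candidate peak is summarised by a circular profile in which each
#' line of evidence occupies an angular sector: the quality index takes the
#' largest share (half the circle by default) and the timing likelihood and
#' the individual neural-network outputs split the other half equally.
#'
#' @param w_quality sector fraction of the quality likelihood (default 0.5).
#' @param w_timing sector fraction of the timing likelihood; default splits
#'   the non-quality remainder equally with the networks.
#' @param w_nn vector of sector fractions, one per network; same default.
#' @param n_nn number of networks when `w_nn` is not given (default 3).
#' @return a `profile_weights` list whose fractions sum to 1.
#' @export
profile_weights <- function(w_quality = 0.5, w_timing = NULL, w_nn = NULL,
                            n_nn = 3) {
  if (is.null(w_timing) && is.null(w_nn)) {
    share <- (1 - w_quality) / (n_nn + 1)
    w_timing <- share
    w_nn <- rep(share, n_nn)
  }
  if (is.null(w_timing) || is.null(w_nn))
    stop_arg("supply both 'w_timing' and 'w_nn', or neither")
  w <- c(w_quality, w_timing, w_nn)
  if (any(w < 0)) stop_arg("profile weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8)
    stop_arg("profile weights must sum to 1 (got %.6f)", sum(w))
  structure(list(w_quality = w_quality, w_timing = w_timing, w_nn = w_nn),
            class = "profile_weights")
}

#' Assemble the circular evidence profile of one annotated peak
#'
#' Sectors appear in fixed order: quality likelihood, then one block per
#' network — subdivided into equal thirds carrying (positive probability |
#' binary outcome | positive probability), so the continuous likelihood
#' flanks the categorical call — and finally the timing likelihood.
#'
#' @param annotation a one-row annotation (list or data-frame row) with
#'   fields `quality_likelihood`, `timing_likelihood`, `nn<i>_p_pos`,
#'   `nn<i>_label`.
#' @param weights a [profile_weights()].
#' @return a `component_profile`: data frame with `component`, `fraction`,
#'   `value`; fractions sum to 1, values lie in [0, 1].
#' @export
assemble_profile <- function(annotation, weights = profile_weights()) {
  stopifnot(inherits(weights, "profile_weights"))
  a <- as.list(annotation)
  comp <- c("quality")
  frac <- c(weights$w_quality)
  val <- c(a$quality_likelihood)
  for (i in seq_along(weights$w_nn)) {
    p <- a[[paste0("nn", i, "_p_pos")]]
    lab <- a[[paste0("nn", i, "_label")]]
    if (is.null(p) || is.null(lab))
      stop_arg("annotation lacks nn%d fields required by the weights", i)
    comp <- c(comp, paste0("nn", i, c("_p", "_label", "_p")))
    frac <- c(frac, rep(weights$w_nn[i] / 3, 3))
    val <- c(val, p, lab, p)
  }
  comp <- c(comp, "timing")
  frac <- c(frac, weights$w_timing)
  val <- c(val, a$timing_likelihood)
  if (any(val < 0 | val > 1)) stop_arg("profile values must lie in [0, 1]")
  structure(data.frame(component = comp, fraction = frac, value = val),
            class = c("component_profile", "data.frame"))
}

#' Composite validity score of a profile
#'
#' The profile is a step function over the circle; its area under the
#' curve, normalized by the full circle area, is the composite score —
#' equivalently the fraction-weighted mean of the sector values, in [0, 1].
#'
#' @param profile a `component_profile` from [assemble_profile()].
#' @return score in [0, 1].
#' @export
composite_score <- function(profile) {
  stopifnot(inherits(profile, "component_profile"))
  sum(profile$fraction * profile$value)
}

#' Burst frequency in bursts per minute
#' @param n_bursts non-negative burst count.
#' @param duration_min recording duration in minutes (> 0).
#' @return bursts/min.
#' @export
burst_frequency <- function(n_bursts, duration_min) {
  if (n_bursts < 0) stop_arg("'n_bursts' must be non-negative")
  if (duration_min <= 0) stop_arg("'duration_min' must be positive")
  n_bursts / duration_min
}

#' Burst incidence in bursts per 100 heartbeats
#' @param n_bursts non-negative burst count.
#' @param n_heartbeats heartbeat count (> 0).
#' @return bursts per 100 heartbeats.
#' @export
burst_incidence <- function(n_bursts, n_heartbeats) {
  if (n_bursts < 0) stop_arg("'n_bursts' must be non-negative")
  if (n_heartbeats <= 0) stop_arg("'n_heartbeats' must be positive")
  100 * n_bursts / n_heartbeats
}

#' Total MSNA: burst frequency times mean burst height
#' @param frequency bursts/min (>= 0).
#' @param mean_height mean burst height in volts (>= 0).
#' @return volts * bursts / min.
#' @export
total_msna <- function(frequency, mean_height) {
  if (frequency < 0 || mean_height < 0)
    stop_arg("inputs must be non-negative")
  frequency * mean_height
}

#' Select bursts whose composite score exceeds a threshold
#'
#' @param annotations annotation data frame with a `composite` column.
#' @param threshold validity threshold in [0, 1] (default 0.5); rows with
#'   `composite > threshold` are retained, order preserved.
#' @return the retained subset.
#' @export
select_valid_bursts <- function(annotations, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop_arg("'threshold' must lie in [0, 1]")
  annotations[annotations$composite > threshold, , drop = FALSE]
}

#' Render a circular evidence profile
#'
#' Optional base-graphics helper drawing the per-peak profile as a filled
#' radial step plot; the composite score never depends on this rendering.
#'
#' @param profile a `component_profile`.
#' @param main plot title.
#' @return the profile, invisibly.
#' @export
plot_profile <- function(profile, main = "peak evidence profile") {
  stopifnot(inherits(profile, "component_profile"))
  theta0 <- 2 * pi * cumsum(c(0, head(profile$fraction, -1)))
  theta1 <- 2 * pi * cumsum(profile$fraction)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  for (k in seq_len(nrow(profile))) {
    th <- seq(theta0[k], theta1[k], length.out = 32)
    r <- profile$value[k]
    graphics::polygon(c(0, r * cos(th)), c(0, r * sin(th)),
                      col = "steelblue", border = NA)
  }
  invisible(profile)
}
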