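#' Spectral signal-quality model
#'
#' Signal quality of an MSNA excerpt is summarised by the median of the
#' magnitude of its discrete Fourier transform: clean excerpts with genuine
#' bursts give narrow magnitude distributions with low medians, whereas
#' electrode-search noise gives broad distributions with markedly higher
#' medians. The likelihood of a median under the valid-signal model is a
#' Gaussian bump centered on the typical valid-signal median.
#'
#' The default center (0.57) and the informational noise reference (about
#' 1.5 and above) correspond to one particular amplifier gain and are meant
#' to be recalibrated on rated excerpts of the target setup — see
#' [calibrate_quality_model()].
#'
#' @param center median of rated valid excerpts (default 0.57).
#' @param sd standard deviation of the likelihood bump (default 0.3).
#' @param window_s length of the analysis window around each peak in
#'   seconds (default 60).
#' @param noise_reference typical noisy-excerpt median, informational only.
#' @return a `quality_model` list.
#' @export
quality_model <- function(center = 0.57, sd = 0.3, window_s = 60,
                          noise_reference = 1.5) {
  assert_scalar_num(center, "center")
  assert_scalar_num(sd, "sd", positive = TRUE)
  assert_scalar_num(window_s, "window_s", positive = TRUE)
  structure(list(center = center, sd = sd, window_s = window_s,
                 noise_reference = noise_reference),
            class = "quality_model")
}

#' Median DFT magnitude of a signal window
#'
#' Computes the unnormalized forward discrete Fourier transform of the raw
#' window (full two-sided spectrum, DC bin included) and returns the median
#' of the absolute values. Exactly scale-equivariant:
#' `spectral_median(c * x) == c * spectral_median(x)` for `c > 0`.
#'
#' @param window numeric vector, length >= 2.
#' @return non-negative scalar.
#' @export
spectral_median <- function(window) {
  if (!is.numeric(window) || length(window) < 2L)
    stop_arg("'window' must be a numeric vector of length >= 2")
  median(Mod(fft(window)))
}

#' Quality index for a set of candidate peaks
#'
#' For each peak, the spectral median of the raw MSNA channel over
#' `peak_time +/- window_s / 2`. Windows crossing the recording boundary are
#' truncated to the available samples and flagged.
#'
#' Because DFT magnitudes of stationary noise grow like the square root of
#' the window length, the median of a truncated window is biased low
#' relative to the model center (which is calibrated for full windows).
#' Truncated medians are therefore rescaled by
#' `sqrt(nominal_length / actual_length)` so they remain comparable;
#' full-length windows are untouched.
#'
#' @param recording an [msna_recording()].
#' @param peaks `candidate_peaks` data frame from [detect_candidate_peaks()].
#' @param model a [quality_model()].
#' @return data frame with columns `quality_median`, `truncated`.
#' @export
quality_index_for_peaks <- function(recording, peaks,
                                    model = quality_model()) {
  stopifnot(inherits(recording, "msna_recording"),
            inherits(model, "quality_model"))
  n <- length(recording$msna)
  half <- round(model$window_s * recording$sample_rate / 2)
  nominal <- 2 * half + 1
  res <- lapply(peaks$index, function(i) {
    lo <- i - half
    hi <- i + half
    trunc <- lo < 1L || hi > n
    seg <- recording$msna[max(1L, lo):min(n, hi)]
    list(m = spectral_median(seg) * sqrt(nominal / length(seg)),
         trunc = trunc)
  })
  data.frame(quality_median = vapply(res, `[[`, numeric(1), "m"),
             truncated = vapply(res, `[[`, logical(1), "trunc"))
}

#' Likelihood of a quality median under the valid-signal model
#'
#' Gaussian density normalized to a maximum of 1:
#' `exp(-(median - center)^2 / (2 * sd^2))`. The max-normalization makes the
#' value deterministic per median, so scores are comparable across
#' recordings.
#'
#' @param median_value spectral median (vectorized).
#' @param model a [quality_model()].
#' @return values in (0, 1].
#' @export
quality_likelihood <- function(median_value, model = quality_model()) {
  stopifnot(inherits(model, "quality_model"))
  exp(-(median_value - model$center)^2 / (2 * model$sd^2))
}

#' Compare quality indices of rated valid vs. invalid excerpt groups
#'
#' Two-sided Mann-Whitney U test, with the U statistic reported for the
#' valid group (number of (valid, invalid) pairs where the valid value is
#' larger, ties counting one half).
#'
#' @param valid_medians,invalid_medians non-empty numeric samples.
#' @return list with `U`, `p_value`, `median_valid`, `median_invalid`, `n`.
#' @export
compare_quality_groups <- function(valid_medians, invalid_medians) {
  if (!length(valid_medians) || !length(invalid_medians))
    stop_arg("both groups must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(valid_medians, invalid_medians, exact = FALSE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_valid = median(valid_medians),
       median_invalid = median(invalid_medians),
       n = c(valid = length(valid_medians),
             invalid = length(invalid_medians)))
}

#' Recalibrate the quality model on rated excerpts
#'
#' The absolute scale of the spectral median depends on amplifier gain and
#' window length, so the model should be fit to rated excerpts from the
#' target setup: the center becomes the median of the valid group; when an
#' invalid (noise) group is supplied, the bump width is set to a quarter of
#' the gap between the group medians (reproducing the 0.3 width that
#' accompanies the 0.57/1.82 reference pair), otherwise to the rescaled
#' default width.
#'
#' @param valid_medians spectral medians of rated valid excerpts.
#' @param invalid_medians optional medians of rated noise excerpts.
#' @param window_s window length carried into the returned model.
#' @return a [quality_model()].
#' @export
calibrate_quality_model <- function(valid_medians, invalid_medians = NULL,
                                    window_s = 60) {
  if (!length(valid_medians)) stop_arg("'valid_medians' must be non-empty")
  center <- median(valid_medians)
  sd_hat <- if (!is.null(invalid_medians) && length(invalid_medians)) {
    gap <- median(invalid_medians) - center
    if (gap <= 0) stop_arg("invalid-group median must exceed valid-group median")
    gap / 4
  } else {
    0.3 / 0.57 * max(center, .Machine$double.eps)
  }
  quality_model(center = center, sd = sd_hat, window_s = window_s,
                noise_reference = if (length(invalid_medians))
                  median(invalid_medians) else center * 1.5 / 0.57)
}
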