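#' Peak-detection parameters
#'
#' The candidate detector is deliberately broad: it keeps every local
#' prominence of the integrated neurogram that looks remotely burst-like, and
#' leaves the discrimination of genuine sympathetic bursts from noise to the
#' downstream probabilistic scoring. Defaults follow the standard broad
#' calibration for integrated MSNA at 1 kHz.
#'
#' @param min_prominence minimum topographic prominence in volts (0.05).
#' @param min_width minimum width at half prominence in ms (100).
#' @param min_distance minimum separation between retained peaks in ms (250);
#'   of two closer peaks the higher survives.
#' @param min_height,max_height raw amplitude bounds in volts (0.05, 0.8).
#' @return a `peak_params` list.
#' @export
peak_params <- function(min_prominence = 0.05, min_width = 100,
                        min_distance = 250, min_height = 0.05,
                        max_height = 0.8) {
  p <- list(min_prominence = min_prominence, min_width = min_width,
            min_distance = min_distance, min_height = min_height,
            max_height = max_height)
  for (nm in names(p)) assert_scalar_num(p[[nm]], nm, positive = TRUE)
  if (p$min_height >= p$max_height)
    stop_arg("min_height must be smaller than max_height")
  structure(p, class = "peak_params")
}

# Left/right base minima of a local maximum: on each side, the lowest sample
# between the peak and the nearest strictly higher sample (or the signal edge
# when no higher terrain exists on that side).
peak_bases <- function(x, i) {
  h <- x[i]
  n <- length(x)
  left <- seq_len(i - 1L)
  hi_l <- left[x[left] > h]
  l_from <- if (length(hi_l)) max(hi_l) + 1L else 1L
  right <- if (i < n) (i + 1L):n else integer(0)
  hi_r <- right[x[right] > h]
  r_to <- if (length(hi_r)) min(hi_r) - 1L else n
  l_rng <- l_from:(i - 1L)
  r_rng <- if (r_to >= i + 1L) (i + 1L):r_to else integer(0)
  l_min_pos <- l_rng[which.min(x[l_rng])]
  r_min_pos <- if (length(r_rng)) r_rng[which.min(x[r_rng])] else i
  list(left_base = l_min_pos, right_base = r_min_pos,
       left_min = x[l_min_pos],
       right_min = if (length(r_rng)) x[r_min_pos] else h)
}

#' Topographic prominence of a local maximum
#'
#' The prominence of a peak is its height above the higher of the two lowest
#' points that separate it from higher terrain on either side; where no
#' higher terrain exists the search extends to the signal edge.
#'
#' @param signal numeric vector (volts).
#' @param index sample index of a local maximum (interior; plateaus count via
#'   any of their samples).
#' @return prominence in the units of `signal`.
#' @export
compute_prominence <- function(signal, index) {
  n <- length(signal)
  if (index < 2L || index > n - 1L)
    stop_arg("index %d is not an interior sample", index)
  h <- signal[index]
  if (signal[index - 1L] > h || signal[index + 1L] > h ||
      (signal[index - 1L] == h && signal[index + 1L] == h))
    stop_arg("index %d is not a local maximum", index)
  b <- peak_bases(signal, index)
  h - max(b$left_min, b$right_min)
}

# Width of a peak at the evaluation height h - rel_height * prominence,
# linearly interpolated between samples, bounded by the peak bases.
# Returned in samples (fractional).
peak_width_samples <- function(x, i, prominence, rel_height = 0.5) {
  eval_h <- x[i] - rel_height * prominence
  b <- peak_bases(x, i)
  j <- i
  while (j > b$left_base && x[j] > eval_h) j <- j - 1L
  left_ip <- as.numeric(j)
  if (x[j] < eval_h) left_ip <- j + (eval_h - x[j]) / (x[j + 1L] - x[j])
  k <- i
  while (k < b$right_base && x[k] > eval_h) k <- k + 1L
  right_ip <- as.numeric(k)
  if (x[k] < eval_h) right_ip <- k - (eval_h - x[k]) / (x[k - 1L] - x[k])
  right_ip - left_ip
}

#' Detect candidate burst peaks in an MSNA trace
#'
#' Finds all interior local maxima (plateaus counted once at their midpoint)
#' and applies, in order: the raw amplitude bounds, the minimum-distance rule
#' (higher peak wins; equal heights keep the earlier), the prominence floor
#' and the width-at-half-prominence floor.
#'
#' @param msna numeric vector of integrated MSNA (volts), or an
#'   [msna_recording()].
#' @param params a [peak_params()] object.
#' @param sample_rate Hz; taken from the recording when one is supplied.
#' @return data frame of class `candidate_peaks` with columns `index`,
#'   `time` (s), `height` (V), `prominence` (V), `width_ms`, sorted by time.
#'   Signals shorter than 3 samples yield an empty result.
#' @export
detect_candidate_peaks <- function(msna, params = peak_params(),
                                   sample_rate = 1000) {
  if (inherits(msna, "msna_recording")) {
    sample_rate <- msna$sample_rate
    msna <- msna$msna
  }
  stopifnot(inherits(params, "peak_params"))
  empty <- data.frame(index = integer(0), time = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width_ms = numeric(0))
  class(empty) <- c("candidate_peaks", "data.frame")
  if (length(msna) < 3L) return(empty)
  idx <- find_local_maxima(msna)
  if (!length(idx)) return(empty)
  h <- msna[idx]
  ok <- h >= params$min_height & h <= params$max_height
  idx <- idx[ok]; h <- h[ok]
  if (!length(idx)) return(empty)
  dist_samples <- params$min_distance * sample_rate / 1000
  keep <- prune_by_distance(idx, h, dist_samples)
  idx <- idx[keep]; h <- h[keep]
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(i) compute_prominence(msna, i), numeric(1))
  ok <- prom >= params$min_prominence
  idx <- idx[ok]; h <- h[ok]; prom <- prom[ok]
  if (!length(idx)) return(empty)
  wid <- vapply(seq_along(idx), function(k) {
    peak_width_samples(msna, idx[k], prom[k]) * 1000 / sample_rate
  }, numeric(1))
  ok <- wid >= params$min_width
  out <- data.frame(index = idx[ok], time = (idx[ok] - 1) / sample_rate,
                    height = h[ok], prominence = prom[ok],
                    width_ms = wid[ok])
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_peaks", "data.frame")
  out
}

#' Extract a fixed-length analysis window around a peak
#'
#' Returns `2 * half_width_ms + 1` samples (at 1 kHz one sample per ms)
#' centered on the peak sample. Samples beyond the recording are zero-padded
#' and the result carries a `truncated` attribute.
#'
#' @param recording an [msna_recording()] (or a bare numeric MSNA vector at
#'   1 kHz).
#' @param peak_index sample index of the window center.
#' @param half_width_ms half window width in ms (> 0).
#' @return numeric vector of length `2 * half_width_ms * sr/1000 + 1` with
#'   attribute `truncated` (logical).
#' @export
extract_window <- function(recording, peak_index, half_width_ms) {
  assert_scalar_num(half_width_ms, "half_width_ms", positive = TRUE)
  sr <- 1000
  x <- recording
  if (inherits(recording, "msna_recording")) {
    sr <- recording$sample_rate
    x <- recording$msna
  }
  hw <- round(half_width_ms * sr / 1000)
  lo <- peak_index - hw
  hi <- peak_index + hw
  n <- length(x)
  out <- numeric(2 * hw + 1)
  src <- max(1L, lo):min(n, hi)
  out[src - lo + 1L] <- x[src]
  attr(out, "truncated") <- lo < 1L || hi > n
  out
}

# Window sized for a classifier input layer. Even input lengths are served by
# the centered odd window with its final sample trimmed, so a 1000-sample
# request yields the peak at position 500.
extract_input_window <- function(recording, peak_index, input_len) {
  if (input_len %% 2L == 1L) {
    extract_window(recording, peak_index, (input_len - 1) / 2)
  } else {
    w <- extract_window(recording, peak_index, input_len / 2)
    tr <- attr(w, "truncated")
    w <- w[-length(w)]
    attr(w, "truncated") <- tr
    w
  }
}

#' Export candidate peaks as a BED-like interval table
#'
#' Three tab-separated columns per peak: start and end of the
#' half-prominence extent in ms, and the peak height in volts.
#'
#' @param peaks a `candidate_peaks` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  start_ms <- peaks$time * 1000 - peaks$width_ms / 2
  end_ms <- peaks$time * 1000 + peaks$width_ms / 2
  data.table::fwrite(data.frame(start_ms = round(start_ms, 3),
                                end_ms = round(end_ms, 3),
                                height_v = peaks$height),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
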