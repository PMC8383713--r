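#' Cardiac-cycle timing model for burst latency
#'
#' Sympathetic bursts are locked to the cardiac cycle: a burst triggered by
#' the baroreflex appears in the peroneal neurogram roughly 1.2-1.5 s after
#' the triggering heartbeat, with the conduction delay growing linearly with
#' body height. The timing likelihood of a candidate peak is a Gaussian bump
#' (default width 200 ms) evaluated at the diastolic reference point of the
#' nearest cardiac cycle; the diastolic nadir sits a fixed offset (default
#' +180 ms) after the ECG R-wave, which allows ECG-only operation when the
#' blood-pressure channel is absent or noisy.
#'
#' The default latency line (`-118.75 + 8.25 * height_cm` ms) spans exactly
#' 1160 ms at 155 cm to 1490 ms at 195 cm, the classical height-dependent
#' latency range; both coefficients are configurable.
#'
#' @param sd_ms width of the timing likelihood in ms (default 200).
#' @param ecg_to_diastole_ms signed offset from the R-wave to the diastolic
#'   nadir in ms (default +180).
#' @param latency_intercept_ms,latency_slope_ms_per_cm coefficients of the
#'   height-latency line.
#' @param default_height_cm height used when none is recorded (175 cm).
#' @return a `timing_model` list.
#' @export
timing_model <- function(sd_ms = 200, ecg_to_diastole_ms = 180,
                         latency_intercept_ms = -118.75,
                         latency_slope_ms_per_cm = 8.25,
                         default_height_cm = 175) {
  assert_scalar_num(sd_ms, "sd_ms", positive = TRUE)
  assert_scalar_num(ecg_to_diastole_ms, "ecg_to_diastole_ms")
  assert_scalar_num(default_height_cm, "default_height_cm", positive = TRUE)
  structure(list(sd_ms = sd_ms, ecg_to_diastole_ms = ecg_to_diastole_ms,
                 latency_intercept_ms = latency_intercept_ms,
                 latency_slope_ms_per_cm = latency_slope_ms_per_cm,
                 default_height_cm = default_height_cm),
            class = "timing_model")
}

#' Detect ECG R-waves
#'
#' Local maxima exceeding a fraction of the robust ECG amplitude (99th
#' percentile above the median), with a refractory period within which only
#' the tallest maximum survives.
#'
#' @param ecg numeric ECG vector.
#' @param sample_rate Hz.
#' @param min_rr_ms refractory period in ms (default 250).
#' @param threshold_frac fraction of the robust amplitude a maximum must
#'   exceed (default 0.5).
#' @return R-wave times in seconds (possibly empty, e.g. for a flat trace).
#' @export
detect_r_waves <- function(ecg, sample_rate = 1000, min_rr_ms = 250,
                           threshold_frac = 0.5) {
  if (length(ecg) < 3L) return(numeric(0))
  base <- median(ecg)
  # 99.9th percentile: high enough to sit on the sparse QRS spikes (a beat
  # occupies ~1% of samples at 1 kHz), robust to isolated artifacts.
  amp <- quantile(ecg, 0.999, names = FALSE) - base
  if (amp <= 0) return(numeric(0))
  thr <- base + threshold_frac * amp
  idx <- find_local_maxima(ecg)
  idx <- idx[ecg[idx] > thr]
  if (!length(idx)) return(numeric(0))
  keep <- prune_by_distance(idx, ecg[idx], min_rr_ms * sample_rate / 1000)
  (sort(idx[keep]) - 1) / sample_rate
}

#' Detect diastolic blood-pressure nadirs
#'
#' Local minima of the continuous blood-pressure trace, retained only when a
#' local maximum (the systolic upstroke) follows within `max_follow_ms` —
#' the standard artifact filter for damped or interrupted pressure signals.
#'
#' @param bp numeric blood-pressure vector (mmHg).
#' @param sample_rate Hz.
#' @param max_follow_ms maximum delay to the following local maximum (150).
#' @return nadir times in seconds.
#' @export
detect_bp_minima <- function(bp, sample_rate = 1000, max_follow_ms = 150) {
  if (length(bp) < 3L) return(numeric(0))
  mins <- find_local_minima(bp)
  if (!length(mins)) return(numeric(0))
  maxs <- find_local_maxima(bp)
  if (!length(maxs)) return(numeric(0))
  follow <- max_follow_ms * sample_rate / 1000
  ok <- vapply(mins, function(m) {
    nxt <- maxs[maxs > m]
    length(nxt) && (nxt[1] - m) <= follow
  }, logical(1))
  (mins[ok] - 1) / sample_rate
}

#' Estimate the ECG-to-diastole offset from paired landmarks
#'
#' Each diastolic nadir is matched with the closest R-wave and the signed
#' difference `t_nadir - t_R` (ms) collected. Gross artifacts are removed in
#' two steps: values with |z| above `z_threshold` (z-scores taken against
#' the median and standard deviation of all raw offsets) are excluded, and
#' the survivors are clipped at `clip_ms`, discarding the long negative
#' tail. The median of the retained offsets is the estimate.
#'
#' @param r_times R-wave times in seconds.
#' @param bp_min_times diastolic nadir times in seconds.
#' @param z_threshold z-score exclusion threshold (default 0.12).
#' @param clip_ms lower clip in ms (default -250).
#' @return list with `median_offset_ms`, `n_raw`, `n_retained`,
#'   `z_threshold`, `clip_ms`.
#' @export
estimate_ecg_bp_offset <- function(r_times, bp_min_times,
                                   z_threshold = 0.12, clip_ms = -250) {
  if (!length(r_times) || !length(bp_min_times))
    stop_arg("both landmark lists must be non-empty")
  nearest <- vapply(bp_min_times, function(t)
    r_times[which.min(abs(r_times - t))], numeric(1))
  offsets <- (bp_min_times - nearest) * 1000
  ctr <- median(offsets)
  scl <- sd(offsets)
  z <- if (is.na(scl) || scl == 0) rep(0, length(offsets)) else
    (offsets - ctr) / scl
  retained <- offsets[abs(z) <= z_threshold]
  retained <- retained[retained >= clip_ms]
  if (!length(retained))
    stop_arg("no offsets retained after z-score and clip filtering")
  list(median_offset_ms = median(retained),
       n_raw = length(offsets), n_retained = length(retained),
       z_threshold = z_threshold, clip_ms = clip_ms)
}

#' Expected burst latency for a subject height
#'
#' Evaluates the height-latency line of the timing model; when no height is
#' available the model default (175 cm) is used.
#'
#' @param height_cm subject height in cm, or `NULL`/`NA`.
#' @param model a [timing_model()].
#' @return expected latency in ms.
#' @export
expected_latency <- function(height_cm = NULL, model = timing_model()) {
  stopifnot(inherits(model, "timing_model"))
  if (is.null(height_cm) || is.na(height_cm))
    height_cm <- model$default_height_cm
  if (!is.numeric(height_cm) || height_cm <= 0)
    stop_arg("'height_cm' must be positive")
  model$latency_intercept_ms + model$latency_slope_ms_per_cm * height_cm
}

#' Cardiac-timing likelihood of candidate peaks
#'
#' The expected trigger time of a peak is its time minus the
#' height-adjusted latency. The likelihood is the max-normalized Gaussian
#' density (width `sd_ms`) evaluated at the diastolic reference of the
#' nearest cardiac cycle, i.e. the closest R-wave plus
#' `ecg_to_diastole_ms`. A burst sitting exactly at
#' R + diastole offset + latency scores 1.
#'
#' @param peak_times numeric vector of peak times (s).
#' @param r_times non-empty vector of R-wave times (s).
#' @param height_cm subject height (cm) or `NULL`.
#' @param model a [timing_model()].
#' @return likelihoods in (0, 1], one per peak.
#' @export
timing_likelihood <- function(peak_times, r_times, height_cm = NULL,
                              model = timing_model()) {
  stopifnot(inherits(model, "timing_model"))
  if (!length(r_times)) stop_arg("'r_times' must be non-empty")
  lat_s <- expected_latency(height_cm, model) / 1000
  centers <- peak_times - lat_s
  vapply(centers, function(ctr) {
    ref <- r_times[which.min(abs(r_times - ctr))] +
      model$ecg_to_diastole_ms / 1000
    d_ms <- (ref - ctr) * 1000
    exp(-d_ms^2 / (2 * model$sd_ms^2))
  }, numeric(1))
}
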