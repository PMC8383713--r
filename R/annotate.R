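#' Annotate every candidate peak of a recording
#'
#' Runs the full scoring pipeline: detect candidate peaks, detect R-waves,
#' compute the spectral quality index and its likelihood, the cardiac-timing
#' likelihood, the classifier probabilities for each supplied network, and
#' the composite validity score from the circular evidence profile.
#'
#' When fewer than three classifiers are supplied the profile weights adapt:
#' the non-quality half of the circle is split equally between the timing
#' sector and the available networks (custom weights can be passed instead).
#' With no classifier, shape evidence is absent and the score rests on
#' quality and timing alone.
#'
#' @param recording an [msna_recording()] (ECG channel required).
#' @param classifiers list of 0-3 trained `msna_nn` models.
#' @param config an [analysis_config()] bundling the component models.
#' @return `msna_annotations`: a data frame with one row per candidate peak
#'   (columns as documented in [write_annotation_table()]).
#' @export
annotate_recording <- function(recording, classifiers = list(),
                               config = analysis_config()) {
  stopifnot(inherits(recording, "msna_recording"))
  if (is.null(recording$ecg))
    stop_arg("annotation requires an ECG channel for the timing model")
  if (length(classifiers) > 3L) stop_arg("at most 3 classifiers supported")
  peaks <- detect_candidate_peaks(recording, config$peak_params)
  weights <- config$profile_weights %||%
    profile_weights(n_nn = length(classifiers))
  if (length(weights$w_nn) != length(classifiers))
    weights <- profile_weights(w_quality = weights$w_quality,
                               n_nn = length(classifiers))
  ann <- data.frame(peak_index = peaks$index, peak_time_s = peaks$time,
                    peak_height_v = peaks$height,
                    prominence_v = peaks$prominence,
                    width_ms = peaks$width_ms)
  npk <- nrow(ann)
  for (i in 1:3) {
    ann[[paste0("nn", i, "_p_pos")]] <- rep(NA_real_, npk)
    ann[[paste0("nn", i, "_label")]] <- rep(NA_integer_, npk)
  }
  r_times <- detect_r_waves(recording$ecg, recording$sample_rate)
  if (!length(r_times))
    stop_arg("no R-waves detected; cannot evaluate burst timing")
  if (npk == 0L) {
    ann$timing_likelihood <- numeric(0)
    ann$quality_median <- numeric(0)
    ann$quality_likelihood <- numeric(0)
    ann$quality_truncated <- logical(0)
    ann$composite <- numeric(0)
    class(ann) <- c("msna_annotations", "data.frame")
    return(ann)
  }
  for (k in seq_along(classifiers)) {
    mod <- classifiers[[k]]
    wins <- t(vapply(peaks$index, function(i)
      extract_input_window(recording, i, mod$config$input_len),
      numeric(mod$config$input_len)))
    pr <- predict_windows(mod, wins)
    ann[[paste0("nn", k, "_p_pos")]] <- pr$p_pos
    ann[[paste0("nn", k, "_label")]] <- pr$label
  }
  ann$timing_likelihood <- timing_likelihood(
    peaks$time, r_times, recording$subject_height_cm, config$timing_model)
  qi <- quality_index_for_peaks(recording, peaks, config$quality_model)
  ann$quality_median <- qi$quality_median
  ann$quality_likelihood <- quality_likelihood(qi$quality_median,
                                               config$quality_model)
  ann$quality_truncated <- qi$truncated
  ann$composite <- vapply(seq_len(npk), function(r) {
    composite_score(assemble_profile(ann[r, ], weights))
  }, numeric(1))
  attr(ann, "r_times") <- r_times
  attr(ann, "duration_s") <- length(recording$msna) / recording$sample_rate
  class(ann) <- c("msna_annotations", "data.frame")
  ann
}

#' Summary statistics of an annotated recording
#'
#' Thresholds the composite score and reports the standard MSNA summary
#' measures: burst frequency (bursts/min), burst incidence (bursts per 100
#' heartbeats), mean burst height and total MSNA (frequency x mean height).
#'
#' @param annotations an `msna_annotations` data frame.
#' @param duration_min recording duration in minutes (taken from the
#'   annotation attributes when available).
#' @param n_heartbeats heartbeat count (defaults to the number of detected
#'   R-waves carried by the annotations).
#' @param threshold composite validity threshold (default 0.5).
#' @return list with `n_peaks`, `n_valid`, `bursts_per_min`,
#'   `bursts_per_100_hb`, `mean_burst_height_v`, `total_msna`.
#' @export
summarize_annotations <- function(annotations, duration_min = NULL,
                                  n_heartbeats = NULL, threshold = 0.5) {
  dur_attr <- attr(annotations, "duration_s")
  duration_min <- duration_min %||%
    (if (is.null(dur_attr)) NULL else dur_attr / 60)
  hb_attr <- attr(annotations, "r_times")
  n_heartbeats <- n_heartbeats %||%
    (if (is.null(hb_attr)) NULL else length(hb_attr))
  if (is.null(duration_min) || !is.finite(duration_min))
    stop_arg("'duration_min' required (annotations carry no duration)")
  valid <- select_valid_bursts(annotations, threshold)
  freq <- burst_frequency(nrow(valid), duration_min)
  mean_h <- if (nrow(valid)) mean(valid$peak_height_v) else 0
  list(n_peaks = nrow(annotations), n_valid = nrow(valid),
       bursts_per_min = freq,
       bursts_per_100_hb = if (!is.null(n_heartbeats) && n_heartbeats > 0)
         burst_incidence(nrow(valid), n_heartbeats) else NA_real_,
       mean_burst_height_v = mean_h,
       total_msna = total_msna(freq, mean_h))
}
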