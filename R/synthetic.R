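#' Configuration of the synthetic microneurography simulator
#'
#' The simulator emulates the statistical structure the analysis relies on,
#' not full hemodynamics: a 1 kHz ECG spike train with jittered RR
#' intervals, a smooth periodic blood-pressure wave whose diastolic nadir
#' sits a fixed offset after each R-wave with the systolic upstroke shortly
#' after, and an MSNA channel of white baseline noise (the amplifier noise
#' floor) plus burst-shaped bumps at a height-dependent latency after a
#' random subset of heartbeats. Optional noise epochs emulate electrode
#' search: MSNA is replaced by high-variance integrated (100 ms smoothed)
#' broadband hash — whose bumps are as wide as genuine bursts — and bursts
#' are suppressed.
#'
#' @param duration_s recording length in seconds.
#' @param rr_mean_ms,rr_jitter_ms mean and Gaussian jitter of the RR
#'   interval (1000 / 30 ms).
#' @param burst_prob probability a heartbeat triggers a burst (0.4).
#' @param burst_height_range_v uniform apex-height range (0.1-0.8 V; must
#'   stay within the detector's 0.05-0.8 V amplitude bounds).
#' @param burst_rise_ms,burst_decay_ms widths of the asymmetric Gaussian
#'   burst shape (100 / 180 ms).
#' @param latency_ms burst latency after the triggering R-wave; default is
#'   the timing-model latency at 175 cm (1325 ms).
#' @param timing_jitter_ms Gaussian jitter of the burst apex (50 ms).
#' @param ecg_to_diastole_ms R-wave to diastolic-nadir offset (+180 ms).
#' @param diastole_to_systole_ms nadir-to-systolic-peak delay (120 ms; must
#'   not exceed the 150 ms artifact-filter window).
#' @param baseline_noise_v sd of the integrated baseline noise (0.02 V).
#' @param search_noise_v sd of electrode-search noise in noise epochs (0.3 V).
#' @param noise_epochs list of `c(start_s, end_s)` intervals.
#' @param bp_diastolic,bp_systolic pressure extremes in mmHg (80 / 120).
#' @param subject_height_cm simulated subject height (175).
#' @param seed master seed; every random stream derives from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 300, rr_mean_ms = 1000,
                             rr_jitter_ms = 30, burst_prob = 0.4,
                             burst_height_range_v = c(0.1, 0.8),
                             burst_rise_ms = 100, burst_decay_ms = 180,
                             latency_ms = NULL, timing_jitter_ms = 50,
                             ecg_to_diastole_ms = 180,
                             diastole_to_systole_ms = 120,
                             baseline_noise_v = 0.02, search_noise_v = 0.3,
                             noise_epochs = list(),
                             bp_diastolic = 80, bp_systolic = 120,
                             subject_height_cm = 175, seed = 1) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  if (burst_prob < 0 || burst_prob > 1)
    stop_arg("'burst_prob' must lie in [0, 1]")
  if (diastole_to_systole_ms > 150)
    stop_arg("'diastole_to_systole_ms' must be <= 150 ms so simulated nadirs pass the artifact filter")
  if (burst_height_range_v[1] < 0.05 || burst_height_range_v[2] > 0.8 ||
      burst_height_range_v[1] > burst_height_range_v[2])
    stop_arg("'burst_height_range_v' must lie within [0.05, 0.8] V")
  latency_ms <- latency_ms %||%
    expected_latency(subject_height_cm, timing_model())
  structure(list(duration_s = duration_s, rr_mean_ms = rr_mean_ms,
                 rr_jitter_ms = rr_jitter_ms, burst_prob = burst_prob,
                 burst_height_range_v = burst_height_range_v,
                 burst_rise_ms = burst_rise_ms,
                 burst_decay_ms = burst_decay_ms,
                 latency_ms = latency_ms,
                 timing_jitter_ms = timing_jitter_ms,
                 ecg_to_diastole_ms = ecg_to_diastole_ms,
                 diastole_to_systole_ms = diastole_to_systole_ms,
                 baseline_noise_v = baseline_noise_v,
                 search_noise_v = search_noise_v,
                 noise_epochs = noise_epochs,
                 bp_diastolic = bp_diastolic, bp_systolic = bp_systolic,
                 subject_height_cm = subject_height_cm,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# White noise smoothed with a 100 ms moving average and rescaled to the
# requested sd — emulating the analog integrator that shapes every channel
# of the neurogram, noise included.
integrated_noise <- function(n, sd_target, sample_rate = 1000,
                             smooth_ms = 100) {
  k <- max(1L, round(smooth_ms * sample_rate / 1000))
  w <- rnorm(n + k)
  sm <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 1))
  sm <- sm[(k + 1):(n + k)]
  sm * sd_target * sqrt(k)
}

# Asymmetric Gaussian burst template evaluated at sample offsets (ms).
burst_shape <- function(dt_ms, rise_ms, decay_ms) {
  s <- ifelse(dt_ms < 0, rise_ms, decay_ms)
  exp(-dt_ms^2 / (2 * s^2))
}

in_epochs <- function(t, epochs) {
  if (!length(epochs)) return(rep(FALSE, length(t)))
  Reduce(`|`, lapply(epochs, function(e) t >= e[1] & t <= e[2]))
}

#' Simulate a recording with ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `recording` (an [msna_recording()]) and `truth`
#'   (`r_times`, `bp_nadir_times`, `burst_times`, `burst_heights`,
#'   `noise_epochs`, all in seconds). Identical seeds give bit-identical
#'   output.
#' @export
simulate_recording <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  sr <- 1000
  n <- round(config$duration_s * sr)
  t <- (seq_len(n) - 1) / sr

  # -- cardiac stream: jittered RR intervals ------------------------------
  r_times <- withr::with_seed(derive_seed(config$seed, 1L), {
    n_beats <- ceiling(config$duration_s * 1000 / config$rr_mean_ms) + 2L
    rr <- config$rr_mean_ms + rnorm(n_beats, 0, config$rr_jitter_ms)
    rr <- pmax(rr, 300)
    rt <- (500 + cumsum(c(0, rr[-n_beats]))) / 1000
    rt[rt < config$duration_s - 0.05]
  })

  # -- ECG: 10 ms triangular R spikes -------------------------------------
  ecg <- numeric(n)
  half_spike <- 5L
  tri <- c(seq(0, 1, length.out = half_spike + 1L),
           seq(1, 0, length.out = half_spike + 1L)[-1])
  for (rt in r_times) {
    i0 <- round(rt * sr) + 1L
    rng <- (i0 - half_spike):(i0 + half_spike)
    ok <- rng >= 1L & rng <= n
    ecg[rng[ok]] <- pmax(ecg[rng[ok]], tri[ok])
  }

  # -- BP: cosine-interpolated knots (nadir -> systolic peak -> nadir) ----
  nadirs <- r_times + config$ecg_to_diastole_ms / 1000
  nadirs <- nadirs[nadirs < config$duration_s - 0.2]
  sys_peaks <- nadirs + config$diastole_to_systole_ms / 1000
  knot_t <- c(0, as.numeric(rbind(nadirs, sys_peaks)))
  knot_v <- c(config$bp_systolic,
              rep(c(config$bp_diastolic, config$bp_systolic),
                  length(nadirs)))
  keep <- !duplicated(knot_t)
  knot_t <- knot_t[keep]; knot_v <- knot_v[keep]
  bp <- numeric(n)
  seg <- findInterval(t, knot_t)
  seg[seg < 1L] <- 1L
  last <- length(knot_t)
  inside <- seg < last
  f <- numeric(n)
  f[inside] <- (t[inside] - knot_t[seg[inside]]) /
    (knot_t[seg[inside] + 1L] - knot_t[seg[inside]])
  v0 <- knot_v[pmin(seg, last)]
  v1 <- knot_v[pmin(seg + 1L, last)]
  bp <- v0 + (v1 - v0) * (1 - cos(pi * f)) / 2
  bp[!inside] <- knot_v[last]

  # -- MSNA: white baseline noise + bursts + integrated search epochs -----
  # Baseline noise is white (the amplifier noise floor): its excursions are
  # far narrower than the 100 ms width filter, so a quiet epoch yields
  # essentially no false candidates. Search noise is integrated broadband
  # hash whose bumps share the width of genuine bursts.
  msna <- withr::with_seed(derive_seed(config$seed, 2L),
                           rnorm(n, 0, config$baseline_noise_v))
  bursts <- withr::with_seed(derive_seed(config$seed, 3L), {
    fire <- rbinom(length(r_times), 1L, config$burst_prob) == 1L
    # bursts are locked to the diastolic nadir of the triggering beat:
    # apex = R + (R-to-diastole offset) + conduction latency + jitter
    apex <- r_times +
      (config$ecg_to_diastole_ms + config$latency_ms) / 1000 +
      rnorm(length(r_times), 0, config$timing_jitter_ms) / 1000
    h <- runif(length(r_times), config$burst_height_range_v[1],
               config$burst_height_range_v[2])
    ok <- fire & apex > 0.3 & apex < config$duration_s - 0.3 &
      !in_epochs(apex, config$noise_epochs)
    list(times = apex[ok], heights = h[ok])
  })
  support_ms <- 4 * max(config$burst_rise_ms, config$burst_decay_ms)
  for (k in seq_along(bursts$times)) {
    i0 <- round(bursts$times[k] * sr) + 1L
    rng <- max(1L, i0 - support_ms):min(n, i0 + support_ms)
    msna[rng] <- msna[rng] + bursts$heights[k] *
      burst_shape((rng - i0) * 1000 / sr, config$burst_rise_ms,
                  config$burst_decay_ms)
  }
  if (length(config$noise_epochs)) {
    noisy <- in_epochs(t, config$noise_epochs)
    search <- withr::with_seed(derive_seed(config$seed, 4L),
                               integrated_noise(n, config$search_noise_v, sr))
    msna[noisy] <- search[noisy]
  }

  rec <- msna_recording(msna = msna, ecg = ecg, bp = bp, sample_rate = sr,
                        subject_height_cm = config$subject_height_cm,
                        subject_id = sprintf("synthetic_seed%d", config$seed))
  truth <- list(r_times = r_times, bp_nadir_times = nadirs,
                burst_times = bursts$times, burst_heights = bursts$heights,
                noise_epochs = config$noise_epochs)
  list(recording = rec, truth = truth)
}

#' Simulate a balanced labeled window set
#'
#' Stand-in for a hand-rated training corpus: positives are burst-shaped
#' bumps (apex at the window center sample) on white baseline noise,
#' negatives are noise alone. `separation` scales the bump apex relative to
#' the noise sd — at 0 the classes are indistinguishable.
#'
#' @param n total window count (>= 4, split evenly).
#' @param input_len window length in samples.
#' @param separation effect size: mean apex height / noise sd (default 6).
#' @param noise_sd noise standard deviation in volts (default 0.1).
#' @param seed RNG seed.
#' @return a [labeled_window_set()] with shuffled, balanced labels.
#' @export
simulate_labeled_windows <- function(n, input_len = 1000, separation = 6,
                                     noise_sd = 0.1, seed = 1) {
  if (n < 4L || n %% 2L != 0L) stop_arg("'n' must be an even count >= 4")
  center <- floor(input_len / 2) + 1L
  dt_ms <- (seq_len(input_len) - center)
  template <- burst_shape(dt_ms, 100, 180)
  withr::with_seed(seed, {
    half <- n %/% 2L
    X <- matrix(rnorm(n * input_len, 0, noise_sd), n, input_len)
    heights <- separation * noise_sd * runif(half, 0.75, 1.25)
    for (i in seq_len(half)) X[i, ] <- X[i, ] + heights[i] * template
    labels <- c(rep(1L, half), rep(0L, half))
    ord <- sample.int(n)
    labeled_window_set(X[ord, , drop = FALSE], labels[ord],
                       provenance = paste0("synthetic_", ord))
  })
}
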