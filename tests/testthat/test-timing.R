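test_that("R-wave detection recovers simulator ground truth within 2 ms", {
  sim <- simulate_recording(synthetic_config(duration_s = 60, seed = 8))
  rt <- detect_r_waves(sim$recording$ecg)
  expect_equal(length(rt), length(sim$truth$r_times))
  err_ms <- vapply(sim$truth$r_times,
                   function(t) min(abs(rt - t)) * 1000, numeric(1))
  expect_lt(max(err_ms), 2)
})

test_that("R-wave detection: flat trace and refractory period", {
  expect_length(detect_r_waves(rep(0, 1000)), 0)
  expect_length(detect_r_waves(rep(3.7, 1000)), 0)
  ecg <- rep(0, 2000)
  ecg[c(400, 550)] <- 1          # 150 ms apart, below the 250 ms refractory
  expect_length(detect_r_waves(ecg), 1)
  ecg2 <- rep(0, 2000)
  ecg2[c(400, 700)] <- 1         # 300 ms apart: both kept
  expect_length(detect_r_waves(ecg2), 2)
})

test_that("BP nadir detection: ground truth, monotone series, follow rule", {
  sim <- simulate_recording(synthetic_config(duration_s = 60, seed = 9))
  nad <- detect_bp_minima(sim$recording$bp)
  hit <- match_within(sim$truth$bp_nadir_times, nad, 0.002)
  expect_gt(mean(hit), 0.98)
  expect_length(detect_bp_minima(seq(10, 0, length.out = 500)), 0)
  t <- seq_len(1000)
  late_max <- -cos(2 * pi * (t - 100) / 440)    # min at 100, max 220 ms later
  expect_length(detect_bp_minima(late_max[1:400]), 0)
  soon_max <- -cos(2 * pi * (t - 100) / 240)    # min at 100, max 120 ms later
  expect_gt(length(detect_bp_minima(soon_max[1:400])), 0)
})

test_that("offset estimation: construction, outlier robustness, empty error", {
  r <- seq(0.5, 119.5, by = 1)
  nad <- r + 0.180
  est <- estimate_ecg_bp_offset(r, nad)
  expect_equal(est$median_offset_ms, 180, tolerance = 0.5)
  expect_equal(est$n_raw, length(nad))
  # 5% gross outliers: some clipped (-400 ms), some z-filtered (+350 ms)
  m <- round(0.05 * length(nad))
  bad <- c(r[seq_len(ceiling(m / 2))] - 0.400,
           r[20 + seq_len(floor(m / 2))] + 0.350)
  est2 <- estimate_ecg_bp_offset(r, c(nad, bad))
  expect_equal(est2$median_offset_ms, 180, tolerance = 2)
  expect_equal(est2$n_raw - est2$n_retained >= m, TRUE)
  expect_error(estimate_ecg_bp_offset(10, 9), "no offsets retained")
})

test_that("offset filters equal brute-force rule application on small instances", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      offs <- c(rnorm(30, 180, 1), sample(c(-400, -3000, 350), 3, TRUE))
      r <- cumsum(rep(10, length(offs)))          # well-separated beats
      nad <- r + offs / 1000
      est <- estimate_ecg_bp_offset(r, nad)
      z <- (offs - median(offs)) / sd(offs)
      manual <- offs[abs(z) <= 0.12]
      manual <- manual[manual >= -250]
      expect_equal(est$n_retained, length(manual))
      expect_equal(est$median_offset_ms, median(manual))
    }
  })
})

test_that("height-latency line: defaults, range, validation", {
  expect_equal(expected_latency(175), 1325)
  expect_equal(expected_latency(NULL), 1325)   # falls back to 175 cm
  expect_equal(expected_latency(NA), 1325)
  lat <- vapply(155:195, expected_latency, numeric(1))
  expect_true(all(lat >= 1160 & lat <= 1490))
  expect_equal(range(lat), c(1160, 1490))
  expect_error(expected_latency(-3), "positive")
})

test_that("timing likelihood closed forms and shape properties", {
  tm <- timing_model()
  lat <- expected_latency(175, tm) / 1000
  r <- 10                                     # single anchor beat
  at <- function(d_ms) r + tm$ecg_to_diastole_ms / 1000 + lat + d_ms / 1000
  expect_equal(timing_likelihood(at(0), r, 175, tm), 1.0, tolerance = 1e-9)
  expect_equal(timing_likelihood(at(200), r, 175, tm), exp(-0.5),
               tolerance = 1e-9)
  expect_equal(timing_likelihood(at(400), r, 175, tm), exp(-2),
               tolerance = 1e-9)
  expect_lt(timing_likelihood(at(600), r, 175, tm), 0.05)  # 3 sd out
  # symmetric in displacement sign, monotone decreasing in |displacement|
  d <- seq(0, 500, by = 25)
  up <- timing_likelihood(at(d), r, 175, tm)
  dn <- timing_likelihood(at(-d), r, 175, tm)
  expect_equal(up, dn, tolerance = 1e-12)
  expect_true(all(diff(up) < 0))
  expect_true(all(up > 0 & up <= 1))
  expect_error(timing_likelihood(1, numeric(0)), "non-empty")
})

test_that("simulator bursts score high; displaced bursts score low", {
  sim <- simulate_recording(synthetic_config(duration_s = 120, seed = 10))
  rt <- detect_r_waves(sim$recording$ecg)
  lik <- timing_likelihood(sim$truth$burst_times, rt,
                           sim$recording$subject_height_cm)
  expect_gt(mean(lik), 0.9)
  displaced <- timing_likelihood(sim$truth$burst_times + 0.600, rt,
                                 sim$recording$subject_height_cm)
  expect_lt(mean(displaced), 0.3)
})
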