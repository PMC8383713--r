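test_that("read_recording ingests delimited text and drops absent channels", {
  path <- withr::local_tempfile(fileext = ".txt")
  n <- 5000
  df <- data.frame(time = (seq_len(n) - 1) / 1000,
                   msna = sin(seq_len(n) / 50) * 0.1,
                   ecg = rep(0, n))
  write.table(df, path, row.names = FALSE, quote = FALSE)
  rec <- read_recording(path)
  expect_s3_class(rec, "msna_recording")
  expect_length(rec$msna, n)
  expect_null(rec$bp)
  expect_false(rec$resampled)
  expect_equal(rec$sample_rate, 1000)
  expect_equal(rec$msna, df$msna, tolerance = 1e-9)
})

test_that("non-1 kHz input is linearly resampled (ramp reproduced exactly)", {
  path <- withr::local_tempfile(fileext = ".txt")
  n <- 5000                               # 500 Hz, ~10 s
  df <- data.frame(time = (seq_len(n) - 1) / 500,
                   msna = (seq_len(n) - 1) / 500)   # ramp = its own time
  write.table(df, path, row.names = FALSE, quote = FALSE)
  rec <- read_recording(path)
  expect_true(rec$resampled)
  expect_equal(rec$sample_rate, 1000)
  expect_length(rec$msna, 2 * n - 1)      # (n-1)/500 s span at 1 kHz
  # linear interpolation of a ramp is the ramp evaluated on the new grid
  expect_equal(rec$msna, rec$time, tolerance = 1e-9)
})

test_that("read_recording rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".txt")
  write.table(data.frame(time = 1:5, volts = 1:5), path,
              row.names = FALSE, quote = FALSE)
  expect_error(read_recording(path), "MSNA column")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("time msna", "0 0.1", "0.001 oops", "0.002 0.2"), path2)
  expect_error(read_recording(path2), "row 2")
  path3 <- withr::local_tempfile(fileext = ".txt")
  file.create(path3)
  expect_error(read_recording(path3), "empty")
})

test_that("recording write/read round-trips within 1e-6 and resampling at 1 kHz is identity", {
  sim <- simulate_recording(synthetic_config(duration_s = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(sim$recording, path)
  back <- read_recording(path)
  expect_false(back$resampled)
  expect_equal(back$msna, sim$recording$msna, tolerance = 1e-6)
  expect_equal(back$bp, sim$recording$bp, tolerance = 1e-6)
  ident <- msnascore:::resample_recording(sim$recording, 1000)
  expect_identical(ident$msna, sim$recording$msna)
})

test_that("annotation table: row counts, empty input, 1e-6 round-trip", {
  ann <- data.frame(peak_index = c(100L, 250L), peak_time_s = c(0.099, 0.249),
                    peak_height_v = c(0.31, 0.52), prominence_v = c(0.2, 0.4),
                    width_ms = c(150.5, 210.25),
                    nn1_p_pos = c(0.9, 0.1), nn2_p_pos = c(0.8, 0.2),
                    nn3_p_pos = c(0.7, 0.3),
                    nn1_label = c(1L, 0L), nn2_label = c(1L, 0L),
                    nn3_label = c(1L, 0L),
                    timing_likelihood = c(0.95, 0.11),
                    quality_median = c(0.6, 1.9),
                    quality_likelihood = c(0.99, 0.01),
                    quality_truncated = c(0, 0), composite = c(0.91, 0.14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotation_table(ann, path)
  expect_length(readLines(path), 3L)
  back <- read_annotation_table(path)
  for (col in names(ann))
    expect_equal(back[[col]], as.numeric(ann[[col]]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  write_annotation_table(ann[0, ], path)
  expect_length(readLines(path), 1L)
  expect_error(write_annotation_table(ann, file.path(tempdir(), "no", "x.csv")),
               "cannot write")
})

test_that("empty config yields documented defaults; overrides propagate", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", path)
  cfg <- load_config(path)
  expect_equal(cfg$peak_params$min_prominence, 0.05)
  expect_equal(cfg$peak_params$min_width, 100)
  expect_equal(cfg$timing_model$sd_ms, 200)
  expect_equal(cfg$timing_model$ecg_to_diastole_ms, 180)
  expect_equal(cfg$quality_model$center, 0.57)
  expect_equal(cfg$quality_model$sd, 0.3)
  expect_equal(cfg$profile_weights$w_quality, 0.5)
  writeLines('{"timing_model": {"default_height_cm": 180}}', path)
  cfg2 <- load_config(path)
  expect_equal(expected_latency(NULL, cfg2$timing_model),
               -118.75 + 8.25 * 180)
})

test_that("config validation: unknown keys and invalid ranges rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"bogus_block": {}}', path)
  expect_error(load_config(path), "unknown config keys")
  writeLines('{"timing_model": {"sd_msec": 100}}', path)
  expect_error(load_config(path), "unknown fields")
  writeLines('{"timing_model": {"sd_ms": -5}}', path)
  expect_error(load_config(path), "sd_ms")
  writeLines('{"quality_model": {"sd": -1}}', path)
  expect_error(load_config(path), "sd")
})

test_that("config JSON round-trip is stable and defaults pass invariants", {
  cfg <- analysis_config(
    peak_params = peak_params(min_prominence = 0.07),
    timing_model = timing_model(sd_ms = 150, default_height_cm = 182),
    quality_model = quality_model(center = 4.2, sd = 0.6),
    profile_weights = profile_weights(w_quality = 0.4))
  path <- withr::local_tempfile(fileext = ".json")
  save_config(cfg, path)
  back <- load_config(path)
  expect_equal(back$peak_params, cfg$peak_params)
  expect_equal(back$timing_model, cfg$timing_model)
  expect_equal(back$quality_model, cfg$quality_model)
  expect_equal(back$profile_weights$w_nn, cfg$profile_weights$w_nn)
  # defaults construct cleanly (every nested validator runs)
  expect_s3_class(analysis_config(), "analysis_config")
})
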