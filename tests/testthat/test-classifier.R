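# Small datasets/architectures keep these fast; the full dtct2 schedule is
# exercised in test-acceptance.R.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(input_len = 200, hidden_widths = c(32, 16, 8, 8, 4), epochs = 5,
         batch_size = 16),
    list(...))
  do.call(classifier_config, args)
}

tiny_windows <- function(n = 120, separation = 8, seed = 5)
  simulate_labeled_windows(n, input_len = 200, separation = separation,
                           seed = seed)

test_that("split arithmetic: 1100 samples at 0.8 give 880/220", {
  lws <- labeled_window_set(matrix(rnorm(1100 * 4), 1100), rep(0:1, 550))
  sp <- split_train_test(lws, 0.8, seed = 1)
  expect_equal(nrow(sp$train$windows), 880)
  expect_equal(nrow(sp$test$windows), 220)
})

test_that("split is a deterministic, exhaustive, disjoint partition", {
  withr::with_seed(3, {
    for (n in c(17, 64, 231)) {
      lws <- labeled_window_set(matrix(rnorm(n * 3), n),
                                rbinom(n, 1, 0.5),
                                provenance = paste0("s", seq_len(n)))
      a <- split_train_test(lws, 0.8, seed = 42)
      b <- split_train_test(lws, 0.8, seed = 42)
      expect_identical(a$train$windows, b$train$windows)
      expect_identical(a$test$labels, b$test$labels)
      got <- sort(c(a$train$provenance, a$test$provenance))
      expect_identical(got, sort(lws$provenance))   # exhaustive + disjoint
    }
  })
  expect_error(split_train_test(
    labeled_window_set(matrix(1, 1, 2), 0), 0.8), "at least 2")
})

test_that("triplication multiplies positives only, preserving content", {
  n <- 880; npos <- 306
  X <- matrix(seq_len(n), n, 3)
  lws <- labeled_window_set(X, c(rep(1, npos), rep(0, n - npos)))
  tri <- triplicate_positives(lws, seed = 1)
  expect_equal(nrow(tri$windows), 1492)             # 880 + 2 * 306
  counts <- table(tri$windows[, 1])
  expect_true(all(counts[as.character(1:npos)] == 3))
  expect_true(all(counts[as.character((npos + 1):n)] == 1))
  none <- labeled_window_set(X[1:10, ], rep(0, 10))
  expect_equal(nrow(triplicate_positives(none)$windows), 10)
  all_pos <- labeled_window_set(X[1:10, ], rep(1, 10))
  expect_equal(nrow(triplicate_positives(all_pos)$windows), 30)
})

test_that("presets define the documented architectures", {
  d1 <- classifier_preset("dtct1")
  expect_equal(d1$input_len, 4001)
  expect_equal(d1$batch_size, 32); expect_equal(d1$epochs, 6)
  d2 <- classifier_preset("dtct2")
  expect_equal(d2$input_len, 1000); expect_equal(d2$epochs, 20)
  expect_true(d2$triplicate)
  d3 <- classifier_preset("dtct3")
  expect_equal(d3$batch_size, 16); expect_equal(d3$epochs, 35)
  for (cfg in list(d1, d2, d3)) {
    expect_length(cfg$hidden_widths, 5)
    m <- build_classifier(cfg, seed = 1)
    expect_equal(nrow(m$W[[1]]), cfg$input_len)
    expect_equal(ncol(m$W[[length(m$W)]]), 2L)
  }
})

test_that("forward pass produces a softmax distribution; input length checked", {
  cfg <- tiny_config()
  m <- build_classifier(cfg, seed = 2)
  w <- rnorm(200)
  p <- predict_window(m, w)
  expect_equal(unname(p["p_negative"] + p["p_positive"]), 1, tolerance = 1e-6)
  expect_equal(unname(p["label"]),
               as.integer(p["p_positive"] >= p["p_negative"]))
  expect_error(predict_window(m, rnorm(199)), "input_len")
})

test_that("training separates a separable synthetic set and is deterministic", {
  lws <- tiny_windows()
  cfg <- tiny_config(seed = 11)
  fit <- train_once(lws, cfg)
  expect_gte(fit$accuracy, 0.9)
  expect_gte(fit$auc, 0.9)
  expect_equal(nrow(fit$curves), cfg$epochs)
  expect_true(all(is.finite(fit$curves$test_loss)))
  fit2 <- train_once(lws, cfg)
  expect_identical(fit$accuracy, fit2$accuracy)
  expect_identical(fit$model$W, fit2$model$W)
  single <- labeled_window_set(lws$windows, rep(0L, nrow(lws$windows)))
  expect_error(train_once(single, cfg), "single class")
})

test_that("repeated training aggregates per-repetition metrics and curves", {
  lws <- tiny_windows(n = 80)
  cfg <- tiny_config(n_repetitions = 3, epochs = 3, seed = 21)
  rep3 <- train_repeated(lws, cfg)
  expect_length(rep3$per_rep_accuracy, 3)
  expect_length(rep3$per_rep_auc, 3)
  expect_equal(nrow(rep3$mean_learning_curve), 3)
  expect_equal(nrow(rep3$mean_loss_curve), 3)
  expect_s3_class(rep3$final_model, "msna_nn")
})

test_that("rank AUC equals explicit pair counting", {
  withr::with_seed(8, {
    for (k in 1:5) {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- 0:1
      s <- round(rnorm(40), 1)               # rounding forces ties
      n1 <- sum(y == 1); n0 <- sum(y == 0)
      expect_equal(roc_auc(s, y),
                   oracle_u_stat(s[y == 1], s[y == 0]) / (n1 * n0))
    }
  })
})

test_that("classifier serialization round-trips bit-stably", {
  lws <- tiny_windows(n = 60)
  fit <- train_once(lws, tiny_config(epochs = 2, seed = 31))
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(fit$model, path)
  back <- load_classifier(path)
  expect_identical(back$W, fit$model$W)
  expect_identical(back$b, fit$model$b)
  w <- lws$windows[1, ]
  expect_identical(predict_window(back, w), predict_window(fit$model, w))
})
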