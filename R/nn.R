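#' Labeled window set for classifier training
#'
#' @param windows numeric matrix, one window per row (volts).
#' @param labels integer vector in \{0, 1\}, one per row.
#' @param provenance optional per-sample subject identifier.
#' @return a `labeled_window_set`.
#' @export
labeled_window_set <- function(windows, labels, provenance = NULL) {
  windows <- as.matrix(windows)
  if (nrow(windows) != length(labels))
    stop_arg("'labels' length (%d) must match rows of 'windows' (%d)",
             length(labels), nrow(windows))
  if (!all(labels %in% c(0, 1))) stop_arg("labels must be 0 or 1")
  structure(list(windows = windows, labels = as.integer(labels),
                 provenance = provenance %||% rep(NA_character_,
                                                  length(labels))),
            class = "labeled_window_set")
}

#' @export
print.labeled_window_set <- function(x, ...) {
  cat(sprintf("<labeled_window_set> %d windows x %d samples (%d positive)\n",
              nrow(x$windows), ncol(x$windows), sum(x$labels)))
  invisible(x)
}

#' Classifier configuration and the three standard presets
#'
#' Three feed-forward burst-shape classifiers are distinguished by their
#' input window and training schedule: `dtct1` consumes the full 4 s window
#' (4001 samples, batch 32, 6 epochs), `dtct2` the central 1 s window
#' (1000 samples, batch 32, 20 epochs, with training positives triplicated
#' to offset class imbalance) and `dtct3` the 1 s window with batch 16 over
#' 35 epochs. All share five dense hidden layers with rectified-linear
#' activations, a dropout layer before the 2-unit softmax output, the adamax
#' optimizer and the sparse categorical cross-entropy loss.
#'
#' @param name preset/identifier.
#' @param input_len window length in samples.
#' @param hidden_widths widths of the dense hidden layers.
#' @param dropout_rate dropout fraction before the output layer.
#' @param batch_size,epochs training schedule.
#' @param learning_rate adamax step size.
#' @param train_frac training fraction of the 80/20 split.
#' @param triplicate logical: triplicate training positives.
#' @param n_repetitions reshuffle-and-retrain repetitions for
#'   [train_repeated()].
#' @param standardize z-score windows before training (off by default; the
#'   raw volt scale is used).
#' @param seed master seed.
#' @return a `classifier_config`.
#' @export
classifier_config <- function(name = "custom", input_len = 1000,
                              hidden_widths = c(256, 128, 64, 32, 16),
                              dropout_rate = 0.5, batch_size = 32,
                              epochs = 20, learning_rate = 0.002,
                              train_frac = 0.8, triplicate = FALSE,
                              n_repetitions = 100, standardize = FALSE,
                              seed = 1) {
  if (any(hidden_widths < 1)) stop_arg("hidden widths must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_arg("'dropout_rate' must be in [0, 1)")
  if (train_frac <= 0 || train_frac >= 1)
    stop_arg("'train_frac' must be in (0, 1)")
  structure(list(name = name, input_len = as.integer(input_len),
                 hidden_widths = as.integer(hidden_widths),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, train_frac = train_frac,
                 triplicate = isTRUE(triplicate),
                 n_repetitions = as.integer(n_repetitions),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' @rdname classifier_config
#' @export
classifier_preset <- function(name = c("dtct1", "dtct2", "dtct3"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    dtct1 = list(input_len = 4001, batch_size = 32, epochs = 6,
                 triplicate = FALSE),
    dtct2 = list(input_len = 1000, batch_size = 32, epochs = 20,
                 triplicate = TRUE),
    dtct3 = list(input_len = 1000, batch_size = 16, epochs = 35,
                 triplicate = FALSE)
  )
  do.call(classifier_config,
          utils::modifyList(c(list(name = name), base), list(...)))
}

#' Random train/test split
#'
#' Partitions a labeled set into disjoint, exhaustive training and testing
#' subsets. The training size is `n * train_frac` rounded half away from
#' zero (1100 samples at 0.8 give 880 training / 220 testing windows).
#'
#' @param dataset a [labeled_window_set()].
#' @param train_frac training fraction in (0, 1).
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return list with elements `train`, `test` (both `labeled_window_set`).
#' @export
split_train_test <- function(dataset, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(dataset, "labeled_window_set"))
  n <- nrow(dataset$windows)
  if (n < 2L) stop_arg("need at least 2 samples to split")
  if (train_frac <= 0 || train_frac >= 1)
    stop_arg("'train_frac' must be in (0, 1)")
  n_train <- as.integer(floor(n * train_frac + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  subset_lws <- function(i) labeled_window_set(
    dataset$windows[i, , drop = FALSE], dataset$labels[i],
    dataset$provenance[i])
  list(train = subset_lws(sort(idx)),
       test = subset_lws(sort(setdiff(seq_len(n), idx))))
}

#' Triplicate the positive class of a training set
#'
#' Each positively labeled window appears three times, negatives once; the
#' result is shuffled with the given seed. Used to offset the low prevalence
#' of genuine bursts among candidates.
#'
#' @param train a [labeled_window_set()].
#' @param seed shuffle seed.
#' @return a [labeled_window_set()] of size `n + 2 * n_positive`.
#' @export
triplicate_positives <- function(train, seed = 1) {
  stopifnot(inherits(train, "labeled_window_set"))
  pos <- which(train$labels == 1L)
  idx <- c(seq_along(train$labels), rep(pos, 2L))
  idx <- withr::with_seed(seed, sample(idx))
  labeled_window_set(train$windows[idx, , drop = FALSE],
                     train$labels[idx], train$provenance[idx])
}

#' Build an untrained burst-shape classifier
#'
#' Feed-forward network: `input_len` inputs, dense ReLU hidden layers of the
#' configured widths, dropout before the final layer, 2-unit softmax output.
#' Weights use He-normal initialization drawn from the given seed.
#'
#' @param config a [classifier_config()].
#' @param seed initialization seed (defaults to the config seed).
#' @return an `msna_nn` model handle.
#' @export
build_classifier <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "classifier_config"))
  dims <- c(config$input_len, config$hidden_widths, 2L)
  withr::with_seed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L],
                             sd = sqrt(2 / dims[l])),
                       nrow = dims[l])
      b[[l]] <- numeric(dims[l + 1L])
    }
    structure(list(W = W, b = b, config = config,
                   center = NULL, scale = NULL),
              class = "msna_nn")
  })
}

#' @export
print.msna_nn <- function(x, ...) {
  dims <- c(x$config$input_len, x$config$hidden_widths, 2L)
  cat(sprintf("<msna_nn '%s'> %s (%d parameters)\n", x$config$name,
              paste(dims, collapse = "-"),
              sum(vapply(x$W, length, numeric(1))) +
                sum(vapply(x$b, length, numeric(1)))))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. Returns probabilities plus (optionally) the layer caches
# needed by backprop. Dropout is applied to the last hidden activation
# (inverted dropout) only when a mask is supplied.
nn_forward <- function(model, X, dropout_mask = NULL, keep_cache = FALSE) {
  L <- length(model$W)
  A <- X
  As <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L - 1L)) {
    A <- pmax(sweep(A %*% model$W[[l]], 2L, model$b[[l]], `+`), 0)
    if (keep_cache) As[[l]] <- A
  }
  if (!is.null(dropout_mask)) {
    A <- A * dropout_mask
    if (keep_cache) As[[L - 1L]] <- A
  }
  Z <- sweep(A %*% model$W[[L]], 2L, model$b[[L]], `+`)
  P <- softmax_rows(Z)
  if (keep_cache) list(P = P, As = As, X = X) else P
}

# Mean sparse categorical cross-entropy of probabilities vs 0/1 labels.
xent_loss <- function(P, y) {
  p_true <- P[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

# One adamax update of all parameters from the gradients of a minibatch.
adamax_step <- function(model, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (l in seq_along(model$W)) {
    for (p in c("W", "b")) {
      g <- grads[[p]][[l]]
      state$m[[p]][[l]] <- beta1 * state$m[[p]][[l]] + (1 - beta1) * g
      state$u[[p]][[l]] <- pmax(beta2 * state$u[[p]][[l]], abs(g))
      model[[p]][[l]] <- model[[p]][[l]] -
        (lr / (1 - beta1^t)) * state$m[[p]][[l]] /
        (state$u[[p]][[l]] + eps)
    }
  }
  list(model = model, state = state)
}

nn_backprop <- function(model, cache, y, dropout_mask, dropout_rate) {
  L <- length(model$W)
  B <- nrow(cache$P)
  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dZ <- (cache$P - Y) / B
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- if (l == 1L) cache$X else cache$As[[l - 1L]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(model$W[[l]])
      if (l == L && !is.null(dropout_mask)) dA <- dA * dropout_mask
      dZ <- dA * (cache$As[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train a classifier once on a fresh split
#'
#' One full training cycle: split the data, optionally triplicate training
#' positives, initialize a fresh network and run minibatch adamax on the
#' sparse categorical cross-entropy for the configured number of epochs.
#' Test accuracy and the rank-based ROC AUC of the positive-class
#' probability are computed on the held-out split; per-epoch train/test
#' accuracy and test loss are recorded.
#'
#' @param dataset a [labeled_window_set()].
#' @param config a [classifier_config()].
#' @param seed seed for this run (split, shuffles, initialization, dropout).
#' @return list with `model`, `accuracy`, `auc`, `curves` (data frame with
#'   one row per epoch: `epoch`, `train_accuracy`, `test_accuracy`,
#'   `test_loss`).
#' @export
train_once <- function(dataset, config, seed = config$seed) {
  stopifnot(inherits(dataset, "labeled_window_set"),
            inherits(config, "classifier_config"))
  if (ncol(dataset$windows) != config$input_len)
    stop_arg("window length %d does not match config input_len %d",
             ncol(dataset$windows), config$input_len)
  sp <- split_train_test(dataset, config$train_frac, seed = seed)
  train <- sp$train
  if (length(unique(train$labels)) < 2L)
    stop_arg("training split contains a single class")
  if (config$triplicate)
    train <- triplicate_positives(train, seed = derive_seed(seed, 1L))
  Xtr <- train$windows
  ytr <- train$labels
  Xte <- sp$test$windows
  yte <- sp$test$labels
  model <- build_classifier(config, seed = derive_seed(seed, 2L))
  if (config$standardize) {
    model$center <- colMeans(Xtr)
    model$scale <- pmax(apply(Xtr, 2L, sd), 1e-8)
    Xtr <- sweep(sweep(Xtr, 2L, model$center), 2L, model$scale, `/`)
    Xte <- sweep(sweep(Xte, 2L, model$center), 2L, model$scale, `/`)
  }
  state <- list(
    m = list(W = lapply(model$W, function(w) w * 0),
             b = lapply(model$b, function(b) b * 0)),
    u = list(W = lapply(model$W, function(w) w * 0),
             b = lapply(model$b, function(b) b * 0)))
  n <- nrow(Xtr)
  p_drop <- config$dropout_rate
  curves <- data.frame(epoch = seq_len(config$epochs), train_accuracy = NA_real_,
                       test_accuracy = NA_real_, test_loss = NA_real_)
  t_step <- 0L
  withr::with_seed(derive_seed(seed, 3L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xtr[rows, , drop = FALSE]
        yb <- ytr[rows]
        mask <- if (p_drop > 0) {
          width <- tail(config$hidden_widths, 1L)
          matrix(rbinom(length(rows) * width, 1L, 1 - p_drop),
                 nrow = length(rows)) / (1 - p_drop)
        } else NULL
        cache <- nn_forward(model, Xb, dropout_mask = mask,
                            keep_cache = TRUE)
        grads <- nn_backprop(model, cache, yb, mask, p_drop)
        t_step <- t_step + 1L
        upd <- adamax_step(model, grads, state, config$learning_rate,
                           t_step)
        model <- upd$model
        state <- upd$state
      }
      Ptr <- nn_forward(model, Xtr)
      Pte <- nn_forward(model, Xte)
      curves$train_accuracy[ep] <- mean((Ptr[, 2L] >= Ptr[, 1L]) == (ytr == 1L))
      curves$test_accuracy[ep] <- mean((Pte[, 2L] >= Pte[, 1L]) == (yte == 1L))
      curves$test_loss[ep] <- xent_loss(Pte, yte)
    }
  })
  Pte <- nn_forward(model, Xte)
  list(model = model,
       accuracy = mean((Pte[, 2L] >= Pte[, 1L]) == (yte == 1L)),
       auc = roc_auc(Pte[, 2L], yte),
       curves = curves)
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outranks a random negative, computed
#' from the rank statistic of the positive-class score with ties averaged.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_arg("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated reshuffle-and-retrain protocol
#'
#' Runs `n_repetitions` independent cycles: reshuffle the train/test split,
#' reset the network, retrain from scratch, and record test accuracy and ROC
#' AUC. Learning and loss curves are averaged across repetitions; the model
#' from the final repetition is retained for application.
#'
#' @param dataset a [labeled_window_set()].
#' @param config a [classifier_config()]; `config$n_repetitions` and
#'   `config$seed` drive the protocol.
#' @return a `training_report` with `per_rep_accuracy`, `per_rep_auc`,
#'   `mean_learning_curve` (per-epoch train/test accuracy),
#'   `mean_loss_curve`, and `final_model`.
#' @export
train_repeated <- function(dataset, config) {
  stopifnot(inherits(config, "classifier_config"))
  reps <- config$n_repetitions
  acc <- numeric(reps)
  auc <- numeric(reps)
  tr_curve <- matrix(0, reps, config$epochs)
  te_curve <- matrix(0, reps, config$epochs)
  loss_curve <- matrix(0, reps, config$epochs)
  model <- NULL
  for (r in seq_len(reps)) {
    fit <- train_once(dataset, config, seed = derive_seed(config$seed, 100L + r))
    acc[r] <- fit$accuracy
    auc[r] <- fit$auc
    tr_curve[r, ] <- fit$curves$train_accuracy
    te_curve[r, ] <- fit$curves$test_accuracy
    loss_curve[r, ] <- fit$curves$test_loss
    model <- fit$model
  }
  structure(list(
    per_rep_accuracy = acc, per_rep_auc = auc,
    mean_learning_curve = data.frame(epoch = seq_len(config$epochs),
                                     train_accuracy = colMeans(tr_curve),
                                     test_accuracy = colMeans(te_curve)),
    mean_loss_curve = data.frame(epoch = seq_len(config$epochs),
                                 test_loss = colMeans(loss_curve)),
    final_model = model, config = config
  ), class = "training_report")
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(paste0("<training_report '%s'> %d repetitions: mean accuracy ",
                     "%.3f, mean ROC AUC %.3f\n"),
              x$config$name, length(x$per_rep_accuracy),
              mean(x$per_rep_accuracy), mean(x$per_rep_auc)))
  invisible(x)
}

#' Score a single window with a trained classifier
#'
#' @param model an `msna_nn` from [train_once()]/[train_repeated()].
#' @param window numeric vector of length `input_len`.
#' @return named vector `c(p_negative, p_positive, label)`; the two
#'   probabilities sum to 1 and `label` is 1 when the positive probability
#'   is at least as large as the negative one.
#' @export
predict_window <- function(model, window) {
  stopifnot(inherits(model, "msna_nn"))
  if (length(window) != model$config$input_len)
    stop_arg("window length %d does not match model input_len %d",
             length(window), model$config$input_len)
  X <- matrix(as.numeric(window), nrow = 1L)
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  P <- nn_forward(model, X)
  c(p_negative = P[1L, 1L], p_positive = P[1L, 2L],
    label = as.integer(P[1L, 2L] >= P[1L, 1L]))
}

# Batched scoring used by the analysis pipeline.
predict_windows <- function(model, windows) {
  X <- as.matrix(windows)
  if (ncol(X) != model$config$input_len)
    stop_arg("window length %d does not match model input_len %d",
             ncol(X), model$config$input_len)
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  P <- nn_forward(model, X)
  data.frame(p_pos = P[, 2L], label = as.integer(P[, 2L] >= P[, 1L]))
}

#' Save / load a trained classifier
#'
#' The model is serialized as a single JSON file holding the configuration
#' and the weights as C99 hexadecimal floating-point literals, so
#' [load_classifier()] restores every parameter bit-stably (decimal JSON
#' numbers would lose the final bits).
#'
#' @param model an `msna_nn`.
#' @param path JSON file path.
#' @return `path` / the restored `msna_nn`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "msna_nn"))
  hexify <- function(v) sprintf("%a", as.numeric(v))
  payload <- list(
    config = unclass(model$config),
    dims = lapply(model$W, dim),
    W = lapply(model$W, hexify),
    b = lapply(model$b, hexify),
    center = if (is.null(model$center)) NULL else hexify(model$center),
    scale = if (is.null(model$scale)) NULL else hexify(model$scale)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, payload$config)
  W <- lapply(seq_along(payload$W), function(l)
    matrix(as.numeric(payload$W[[l]]), nrow = payload$dims[[l]][1]))
  structure(list(W = W, b = lapply(payload$b, as.numeric),
                 config = cfg,
                 center = if (is.null(payload$center)) NULL else
                   as.numeric(payload$center),
                 scale = if (is.null(payload$scale)) NULL else
                   as.numeric(payload$scale)),
            class = "msna_nn")
}
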