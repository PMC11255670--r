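#' Classifier configuration
#'
#' Architecture and training hyper-parameters of the sleep-state classifier:
#' a bidirectional GRU with two layers of 10 hidden units per direction and
#' a 3-class softmax head over (WAKE, N1REM, N2N3), reading the five
#' normalized features. Each recording is one full training sequence, so the
#' bidirectional context spans the whole night. Training minimizes 3-class
#' cross-entropy with Adam, full-batch, with early stopping on a
#' recording-level inner validation split. Class weighting is available but
#' off by default (it was evaluated and brought no overall improvement);
#' the infant's age is deliberately not an input for the same reason.
#'
#' @param hidden_units Hidden units per layer and direction (default 10).
#' @param layers Stacked bidirectional layers (default 2).
#' @param input_features Number of input features (default 5).
#' @param learning_rate Adam step size.
#' @param max_passes Maximum full-batch passes.
#' @param patience Early-stopping patience (passes without validation
#'   improvement).
#' @param val_fraction Fraction of training recordings held out for early
#'   stopping (recording-level split).
#' @param class_weights Weight classes by inverse frequency (default off).
#' @param seed RNG seed controlling initialization and the inner split.
#' @return A list of class `model_config`.
#' @export
model_config <- function(hidden_units = 10, layers = 2, input_features = 5,
                         learning_rate = 1e-3, max_passes = 300, patience = 20,
                         val_fraction = 0.2, class_weights = FALSE, seed = 1L) {
  structure(list(hidden_units = as.integer(hidden_units),
                 layers = as.integer(layers),
                 input_features = as.integer(input_features),
                 classes = 3L, bidirectional = TRUE,
                 learning_rate = learning_rate,
                 max_passes = as.integer(max_passes),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "model_config")
}

as_feature_seq <- function(features, n_features) {
  x <- as.matrix(tibble::as_tibble(features)[CLASSIFIER_FEATURES[seq_len(n_features)]])
  if (anyNA(x)) abort("normalized feature sequence contains missing values")
  unname(x)
}

as_label_int <- function(labels) {
  if (inherits(labels, "hypnogram")) {
    if (attr(labels, "scheme") != "merged3") {
      abort("training labels must use the merged 3-state scheme; see merge_to_three_state()")
    }
    labels <- as.character(labels$label)
  }
  labels <- as.character(labels)
  if (!all(labels %in% STATES3)) abort("labels outside the 3-state alphabet")
  match(labels, STATES3) - 1L
}

#' Train the bidirectional GRU sleep-state classifier
#'
#' @param data A list of recordings, each a list with `features` (normalized
#'   sequence from [apply_normalizer()]) and `labels` (3-state
#'   [hypnogram()], factor or character vector), aligned per 30-s epoch.
#' @param config A [model_config()].
#' @return A fitted model of class `sleep_gru`.
#' @export
train_classifier <- function(data, config = model_config()) {
  stopifnot(length(data) >= 2)
  ids <- purrr::map_chr(seq_along(data), function(i) {
    id <- attr(data[[i]]$features, "recording_id")
    if (is.null(id)) sprintf("recording %d", i) else id
  })
  X <- lapply(data, function(d) as_feature_seq(d$features, config$input_features))
  y <- lapply(data, function(d) as_label_int(d$labels))
  for (i in seq_along(X)) {
    if (nrow(X[[i]]) != length(y[[i]])) {
      abort(sprintf("features (%d epochs) and labels (%d epochs) are misaligned in %s",
                    nrow(X[[i]]), length(y[[i]]), ids[i]))
    }
  }

  n <- length(X)
  n_val <- floor(config$val_fraction * n)
  split <- withr::with_seed(config$seed, sample.int(n))
  val_idx <- if (n_val >= 1) split[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(split, val_idx)

  cw <- c(1, 1, 1)
  if (config$class_weights) {
    counts <- tabulate(unlist(y[tr_idx]) + 1L, nbins = 3L)
    counts[counts == 0] <- 1L
    cw <- sum(counts) / (3 * counts)
  }

  p0 <- cpp_gru_init(config$input_features, config$hidden_units,
                     config$layers, config$classes, config$seed)
  fit <- cpp_gru_train(p0, X[tr_idx], y[tr_idx], X[val_idx], y[val_idx],
                       config$input_features, config$hidden_units,
                       config$layers, config$classes,
                       cw, config$learning_rate, config$max_passes,
                       config$patience)
  structure(list(params = as.numeric(fit$params),
                 config = config,
                 class_weights = cw,
                 classes = STATES3,
                 n_recordings = n,
                 recording_ids = ids,
                 val_recordings = ids[val_idx],
                 best_iter = fit$best_iter,
                 best_score = fit$best_score,
                 train_loss = as.numeric(fit$train_loss),
                 val_loss = as.numeric(fit$val_loss)),
            class = "sleep_gru")
}

#' Predict per-epoch class probabilities
#'
#' @param model A fitted `sleep_gru` model.
#' @param features A normalized feature sequence ([apply_normalizer()]).
#' @return A tibble of class `class_probabilities` with columns `epoch,
#'   p_wake, p_n1rem, p_n2n3`; each row is a probability simplex. If the
#'   source recording had no valid epochs at all, the result carries the
#'   metadata flag `all_invalid` so downstream users can mask it.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "sleep_gru"))
  cfg <- model$config
  X <- as_feature_seq(features, cfg$input_features)
  if (ncol(X) != cfg$input_features) {
    abort(sprintf("model expects %d features, got %d", cfg$input_features, ncol(X)))
  }
  P <- cpp_gru_predict(model$params, X, cfg$input_features, cfg$hidden_units,
                       cfg$layers, cfg$classes)
  structure(tibble::tibble(epoch = seq_len(nrow(P)),
                           p_wake = P[, 1], p_n1rem = P[, 2], p_n2n3 = P[, 3]),
            recording_id = attr(features, "recording_id"),
            all_invalid = isTRUE(attr(features, "all_invalid")),
            class = c("class_probabilities", class(tibble::tibble())))
}

#' @export
print.sleep_gru <- function(x, ...) {
  cat(sprintf("<sleep_gru> bidirectional GRU: %d layer(s) x %d hidden units, %d features -> %d classes\n",
              x$config$layers, x$config$hidden_units,
              x$config$input_features, x$config$classes))
  cat(sprintf("  trained on %d recording(s); best pass %d (score %.4f)\n",
              x$n_recordings, x$best_iter, x$best_score))
  invisible(x)
}

#' Tidy summaries of a fitted classifier
#'
#' `tidy()` returns one row per parameter block (layer, direction, matrix)
#' with element counts and magnitude summaries; `glance()` returns a one-row
#' model summary.
#'
#' @param x A `sleep_gru` model.
#' @param ... Unused.
#' @export
tidy.sleep_gru <- function(x, ...) {
  cfg <- x$config
  H <- cfg$hidden_units
  blocks <- list()
  off <- 0
  take <- function(n) {
    v <- x$params[(off + 1):(off + n)]
    off <<- off + n
    v
  }
  for (l in seq_len(cfg$layers)) {
    I <- if (l == 1) cfg$input_features else 2 * H
    for (dir in c("forward", "backward")) {
      for (blk in c("W", "U", "b")) {
        n <- switch(blk, W = 3 * H * I, U = 3 * H * H, b = 3 * H)
        v <- take(n)
        blocks[[length(blocks) + 1]] <- tibble::tibble(
          layer = l, direction = dir, block = blk, n = n,
          mean = mean(v), sd = sd(v), max_abs = max(abs(v)))
      }
    }
  }
  v <- take(cfg$classes * 2 * H)
  blocks[[length(blocks) + 1]] <- tibble::tibble(
    layer = NA_integer_, direction = "output", block = "Wo",
    n = length(v), mean = mean(v), sd = sd(v), max_abs = max(abs(v)))
  v <- take(cfg$classes)
  blocks[[length(blocks) + 1]] <- tibble::tibble(
    layer = NA_integer_, direction = "output", block = "bo",
    n = length(v), mean = mean(v), sd = sd(v), max_abs = max(abs(v)))
  dplyr::bind_rows(blocks)
}

#' @rdname tidy.sleep_gru
#' @export
glance.sleep_gru <- function(x, ...) {
  tibble::tibble(
    n_params = length(x$params),
    n_recordings = x$n_recordings,
    layers = x$config$layers,
    hidden_units = x$config$hidden_units,
    best_pass = x$best_iter,
    best_score = x$best_score,
    final_train_loss = tail(x$train_loss, 1),
    passes_run = length(x$train_loss))
}

#' Save / load a classifier checkpoint
#'
#' Single-file JSON checkpoint with a versioned header carrying the model
#' configuration, the normalization parameters used at training time, and
#' the flat weight vector at full precision.
#'
#' @param model A `sleep_gru` model.
#' @param normalizer The `normalizer_params` the model was trained with
#'   (stored so prediction on raw feature logs is self-contained).
#' @param path File path.
#' @export
save_model <- function(model, path, normalizer = NULL) {
  stopifnot(inherits(model, "sleep_gru"))
  payload <- list(
    format = "imusleep-gru-checkpoint",
    version = 1L,
    package_version = as.character(utils::packageVersion("imusleep")),
    config = unclass(model$config),
    class_weights = model$class_weights,
    classes = model$classes,
    best_iter = model$best_iter,
    params = model$params)
  if (!is.null(normalizer)) {
    payload$normalizer <- list(params = normalizer$params,
                               config = unclass(normalizer$config))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "imusleep-gru-checkpoint")) {
    format_error("not an imusleep GRU checkpoint file")
  }
  cfg <- payload$config
  config <- model_config(hidden_units = cfg$hidden_units, layers = cfg$layers,
                         input_features = cfg$input_features,
                         learning_rate = cfg$learning_rate,
                         max_passes = cfg$max_passes, patience = cfg$patience,
                         val_fraction = cfg$val_fraction,
                         class_weights = cfg$class_weights, seed = cfg$seed)
  model <- structure(list(params = as.numeric(payload$params),
                          config = config,
                          class_weights = payload$class_weights,
                          classes = payload$classes,
                          n_recordings = NA_integer_,
                          best_iter = payload$best_iter,
                          best_score = NA_real_,
                          train_loss = numeric(0), val_loss = numeric(0)),
                     class = "sleep_gru")
  normalizer <- NULL
  if (!is.null(payload$normalizer)) {
    normalizer <- structure(
      list(params = tibble::as_tibble(payload$normalizer$params),
           config = structure(payload$normalizer$config, class = "normalizer_config")),
      class = "normalizer_params")
  }
  list(model = model, normalizer = normalizer)
}
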