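fold_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 1e6 * 7919 + i * 104729) %% 2147483629)
}

#' Leave-one-subject-out cross-validation of the sleep-state classifier
#'
#' For each recording in the cohort, a normalizer and a classifier are
#' fitted on all *other* recordings and applied to the held-out one. The
#' held-out recording therefore contributes to neither the normalization
#' statistics nor any gradient update — no test-fold leakage, by
#' construction. One master seed fans out to deterministic per-fold seeds,
#' so a repeated run is bit-identical.
#'
#' @param cohort A list of recordings, each a list with `features`
#'   (a [feature_matrix()]) and `labels` (a [hypnogram()]; 5-state input is
#'   merged to 3 states automatically).
#' @param config A [model_config()]; `config$seed` is the master seed.
#' @param norm_config A [normalizer_config()].
#' @return An object of class `losocv_result` with per-recording
#'   probabilities, predictions, metrics and the pooled confusion matrix.
#'   Use [tidy()] for per-recording metrics and [glance()] for the group
#'   summary.
#' @export
losocv <- function(cohort, config = model_config(),
                   norm_config = normalizer_config()) {
  stopifnot(length(cohort) >= 3)
  ids <- purrr::map_chr(seq_along(cohort), function(i) {
    id <- attr(cohort[[i]]$features, "recording_id")
    if (is.null(id)) sprintf("recording%02d", i) else id
  })
  labels3 <- lapply(cohort, function(rec) {
    h <- rec$labels
    if (!inherits(h, "hypnogram")) h <- hypnogram(h)
    if (attr(h, "scheme") == "aasm5") h <- merge_to_three_state(h)
    h
  })
  for (i in seq_along(cohort)) {
    if (nrow(cohort[[i]]$features) != nrow(labels3[[i]])) {
      abort(sprintf("features (%d epochs) and hypnogram (%d epochs) are misaligned in %s",
                    nrow(cohort[[i]]$features), nrow(labels3[[i]]), ids[i]))
    }
  }

  folds <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    train_idx <- setdiff(seq_along(cohort), i)
    norm <- fit_normalizer(lapply(cohort[train_idx], `[[`, "features"), norm_config)
    train_data <- lapply(train_idx, function(j) {
      list(features = apply_normalizer(cohort[[j]]$features, norm),
           labels = labels3[[j]])
    })
    fold_cfg <- config
    fold_cfg$seed <- fold_seed(config$seed, i)
    model <- train_classifier(train_data, fold_cfg)
    test_feats <- apply_normalizer(cohort[[i]]$features, norm)
    proba <- predict_proba(model, test_feats)
    pred <- discretize(proba)
    cm <- confusion_matrix(labels3[[i]], pred)
    folds[[i]] <- list(recording_id = ids[i],
                       probabilities = proba,
                       predicted = pred,
                       truth = labels3[[i]],
                       normalizer = norm,
                       confusion = cm,
                       acc = accuracy(cm),
                       mcc = mcc(cm),
                       best_iter = model$best_iter)
  }

  metrics <- purrr::map_dfr(folds, function(f) {
    tibble::tibble(recording_id = f$recording_id, acc = f$acc, mcc = f$mcc,
                   n_epochs = nrow(f$truth))
  })
  pooled <- Reduce(`+`, lapply(folds, `[[`, "confusion"))
  class(pooled) <- "confusion_matrix"
  structure(list(folds = folds, metrics = metrics, confusion = pooled,
                 config = config, norm_config = norm_config),
            class = "losocv_result")
}

#' @export
print.losocv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<losocv_result> %d folds, %d epochs\n", nrow(x$metrics), sum(x$metrics$n_epochs)))
  cat(sprintf("  median accuracy %.3f (IQR %.3f-%.3f), median MCC %.3f (IQR %.3f-%.3f)\n",
              g$median_acc, g$q25_acc, g$q75_acc, g$median_mcc, g$q25_mcc, g$q75_mcc))
  invisible(x)
}

#' Tidy methods for cross-validation results
#'
#' `tidy()` returns the per-recording accuracy and MCC; `glance()` the group
#' medians and IQRs plus the pooled-epoch accuracy and MCC.
#'
#' @param x A `losocv_result`.
#' @param ... Unused.
#' @export
tidy.losocv_result <- function(x, ...) x$metrics

#' @rdname tidy.losocv_result
#' @export
glance.losocv_result <- function(x, ...) {
  fs <- fold_summary(x$metrics)
  acc <- fs[fs$metric == "acc", ]
  mc <- fs[fs$metric == "mcc", ]
  tibble::tibble(n_recordings = nrow(x$metrics),
                 n_epochs = sum(x$metrics$n_epochs),
                 median_acc = acc$median, q25_acc = acc$q25, q75_acc = acc$q75,
                 median_mcc = mc$median, q25_mcc = mc$q25, q75_mcc = mc$q75,
                 pooled_acc = accuracy(x$confusion),
                 pooled_mcc = mcc(x$confusion))
}
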