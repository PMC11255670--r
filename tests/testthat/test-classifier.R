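# The recurrent network is implemented from scratch, so its gradients are
# verified against central finite differences before anything else trusts it.
test_that("analytic GRU gradients match finite differences", {
  withr::with_seed(1, {
    inp <- 3; hid <- 4; lay <- 2; cls <- 3
    p <- imusleep:::cpp_gru_init(inp, hid, lay, cls, 7)
    X <- list(matrix(rnorm(18), 6, 3), matrix(rnorm(12), 4, 3))
    y <- list(sample(0:2, 6, TRUE), sample(0:2, 4, TRUE))
    cw <- c(1, 1.4, 0.7)
    lg <- imusleep:::cpp_gru_loss_grad(p, X, y, inp, hid, lay, cls, cw, TRUE)
    eps <- 1e-6
    idx <- sample(length(p), 40)
    num <- vapply(idx, function(i) {
      pp <- p; pp[i] <- pp[i] + eps
      pm <- p; pm[i] <- pm[i] - eps
      (imusleep:::cpp_gru_loss_grad(pp, X, y, inp, hid, lay, cls, cw, FALSE)$loss -
         imusleep:::cpp_gru_loss_grad(pm, X, y, inp, hid, lay, cls, cw, FALSE)$loss) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(lg$grad[idx] - num)), 1e-7)
  })
})

test_that("training separates a well-separated synthetic cohort", {
  cohort <- normalized_cohort(feature_cohort(n_rec = 5, n_epochs = 120, seed = 21))
  model <- train_classifier(cohort, model_config(seed = 3))
  correct <- 0; total <- 0
  for (rec in cohort) {
    pred <- discretize(predict_proba(model, rec$features))
    correct <- correct + sum(pred$label == rec$labels$label)
    total <- total + nrow(pred)
  }
  expect_gte(correct / total, 0.95)
})

test_that("per-epoch label shuffling drops held-out accuracy to chance", {
  # enough held-out epochs that binomial noise is well inside the ±5-point band
  cohort <- feature_cohort(n_rec = 6, n_epochs = 400, seed = 22)
  shuffled <- withr::with_seed(23, lapply(cohort, function(r) {
    lab <- sample(as.character(r$labels$label))
    list(features = r$features, labels = hypnogram(lab, scheme = "merged3"))
  }))
  nshuf <- normalized_cohort(shuffled)
  model <- train_classifier(nshuf[1:5], model_config(seed = 4, max_passes = 100))
  held <- nshuf[[6]]
  pred <- discretize(predict_proba(model, held$features))
  acc <- mean(pred$label == held$labels$label)
  priors <- table(factor(unlist(lapply(shuffled[1:5], function(r) as.character(r$labels$label))),
                         levels = c("WAKE", "N1REM", "N2N3")))
  majority <- max(priors) / sum(priors)
  expect_lt(abs(acc - majority), 0.05 + 1e-9)
})

test_that("training and prediction are deterministic under a fixed seed", {
  cohort <- normalized_cohort(feature_cohort(n_rec = 4, n_epochs = 60, seed = 25))
  m1 <- train_classifier(cohort, model_config(seed = 11, max_passes = 60))
  m2 <- train_classifier(cohort, model_config(seed = 11, max_passes = 60))
  expect_identical(m1$params, m2$params)
  p1 <- predict_proba(m1, cohort[[1]]$features)
  p2 <- predict_proba(m2, cohort[[1]]$features)
  expect_identical(p1, p2)
})

test_that("probability outputs are simplex rows of the input length", {
  cohort <- normalized_cohort(feature_cohort(n_rec = 4, n_epochs = 60, seed = 26))
  model <- train_classifier(cohort, model_config(seed = 2, max_passes = 40))
  pr <- predict_proba(model, cohort[[2]]$features)
  expect_equal(nrow(pr), 60)
  pm <- as.matrix(pr[c("p_wake", "p_n1rem", "p_n2n3")])
  expect_true(all(pm >= 0))
  expect_equal(rowSums(pm), rep(1, 60), tolerance = 1e-6)
})

test_that("feature-count mismatches and misaligned labels are rejected", {
  cohort <- normalized_cohort(feature_cohort(n_rec = 4, n_epochs = 60, seed = 27))
  model <- train_classifier(cohort, model_config(seed = 2, max_passes = 20))
  broken <- cohort[[1]]$features[, -2]
  expect_error(predict_proba(model, broken))
  bad <- cohort
  bad[[2]]$labels <- hypnogram(rep("WAKE", 10), scheme = "merged3")
  expect_error(train_classifier(bad, model_config(seed = 2)), "misaligned")
})

test_that("class weighting does not decrease minority-class recall", {
  # imbalanced cohort: wake is rare and overlaps the light-sleep cluster
  means <- list(WAKE = c(0.8, 41, 3.0, 0.33, 0.50),
                N1REM = c(0.3, 38, 4.0, 0.25, 0.55),
                N2N3 = c(0.1, 30, 6.0, 0.08, 0.90))
  cohort <- normalized_cohort(feature_cohort(
    n_rec = 6, n_epochs = 150, sd = 0.9, seed = 28,
    state_means = means, wake_weight = 0.12))
  train <- cohort[1:4]
  test <- cohort[5:6]
  recall_wake <- function(class_weights) {
    model <- train_classifier(train, model_config(seed = 5, max_passes = 120,
                                                  class_weights = class_weights))
    cm <- Reduce(`+`, lapply(test, function(r) {
      confusion_matrix(r$labels, discretize(predict_proba(model, r$features)))
    }))
    class(cm) <- "confusion_matrix"
    class_recalls(cm)$recall[1]
  }
  r_plain <- recall_wake(FALSE)
  r_weighted <- recall_wake(TRUE)
  expect_gte(r_weighted, r_plain)
})

test_that("LOSOCV builds one leakage-free fold per recording", {
  cohort <- feature_cohort(n_rec = 3, n_epochs = 80, seed = 31)
  res <- losocv(cohort, model_config(seed = 6, max_passes = 40))
  expect_equal(nrow(res$metrics), 3)
  expect_length(res$folds, 3)
  for (i in 1:3) {
    expect_equal(nrow(res$folds[[i]]$probabilities), 80)
    expect_equal(res$folds[[i]]$recording_id, sprintf("fc%02d", i))
  }
  # shifting one recording's features changes its fold's normalizer
  # relative to the all-recordings normalizer (which sees the shift)
  shifted <- cohort
  df <- tibble::as_tibble(shifted[[2]]$features)
  df$resp_rate <- df$resp_rate + 25
  shifted[[2]]$features <- feature_matrix(df, recording_id = "fc02")
  res2 <- losocv(shifted, model_config(seed = 6, max_passes = 20))
  fold_norm <- res2$folds[[2]]$normalizer # fitted without the shifted recording
  global_norm <- fit_normalizer(lapply(shifted, `[[`, "features"))
  expect_false(isTRUE(all.equal(
    fold_norm$params$center[fold_norm$params$feature == "resp_rate"],
    global_norm$params$center[global_norm$params$feature == "resp_rate"])))
  # oracle: the fold normalizer equals one fitted on the other two recordings
  oracle <- fit_normalizer(lapply(shifted[-2], `[[`, "features"))
  expect_equal(fold_norm$params, oracle$params)
})

test_that("a seeded LOSOCV run is fully reproducible", {
  cohort <- feature_cohort(n_rec = 3, n_epochs = 60, seed = 32)
  r1 <- losocv(cohort, model_config(seed = 13, max_passes = 30))
  r2 <- losocv(cohort, model_config(seed = 13, max_passes = 30))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$folds[[1]]$probabilities, r2$folds[[1]]$probabilities)
})

test_that("model checkpoints round-trip through save_model/load_model", {
  cohort <- feature_cohort(n_rec = 4, n_epochs = 60, seed = 33)
  norm <- fit_normalizer(lapply(cohort, `[[`, "features"))
  ncoh <- lapply(cohort, function(r) list(features = apply_normalizer(r$features, norm),
                                          labels = r$labels))
  model <- train_classifier(ncoh, model_config(seed = 2, max_passes = 30))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path, normalizer = norm)
  ck <- load_model(path)
  expect_equal(ck$model$params, model$params)
  expect_equal(ck$normalizer$params, norm$params)
  p1 <- predict_proba(model, ncoh[[1]]$features)
  p2 <- predict_proba(ck$model, ncoh[[1]]$features)
  expect_equal(p1, p2)
})
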