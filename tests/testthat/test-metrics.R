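states3 <- c("WAKE", "N1REM", "N2N3")

rand_labels <- function(n, seed) {
  withr::with_seed(seed, list(t = sample(states3, n, TRUE, c(0.2, 0.45, 0.35)),
                              p = sample(states3, n, TRUE, c(0.3, 0.3, 0.4))))
}

# independent oracle: explicit pair counting
brute_cm <- function(t, p) {
  m <- matrix(0L, 3, 3, dimnames = list(true = states3, pred = states3))
  for (i in seq_along(t)) m[t[i], p[i]] <- m[t[i], p[i]] + 1L
  m
}

# independent oracle: MCC as the correlation of one-hot encodings
cov_mcc <- function(t, p) {
  X <- sapply(states3, function(s) as.numeric(t == s))
  Y <- sapply(states3, function(s) as.numeric(p == s))
  cxy <- sum(diag(stats::cov(X, Y)))
  cxx <- sum(diag(stats::cov(X, X)))
  cyy <- sum(diag(stats::cov(Y, Y)))
  cxy / sqrt(cxx * cyy)
}

test_that("confusion matrices match brute-force pair counting", {
  lp <- rand_labels(1000, seed = 41)
  cm <- confusion_matrix(lp$t, lp$p)
  expect_equal(unclass(cm), brute_cm(lp$t, lp$p), ignore_attr = TRUE)
  expect_equal(sum(cm), 1000)

  ident <- confusion_matrix(states3, states3)
  expect_equal(diag(unclass(ident)), setNames(rep(1L, 3), states3))
  one_cell <- confusion_matrix(rep("WAKE", 5), rep("N2N3", 5))
  expect_equal(unclass(one_cell)["WAKE", "N2N3"], 5L)
  expect_equal(sum(one_cell), 5)
  expect_error(confusion_matrix(states3, states3[1:2]), "differ in length")
})

test_that("accuracy equals the epoch-wise agreement fraction", {
  lp <- rand_labels(1000, seed = 42)
  expect_equal(accuracy(confusion_matrix(lp$t, lp$p)), mean(lp$t == lp$p))
  diag10 <- confusion_matrix(rep(states3, each = 10), rep(states3, each = 10))
  expect_equal(accuracy(diag10), 1)
  off <- confusion_matrix(rep("WAKE", 4), rep("N1REM", 4))
  expect_equal(accuracy(off), 0)
})

test_that("multiclass MCC matches the covariance-form oracle", {
  for (seed in 43:47) {
    lp <- rand_labels(500, seed = seed)
    expect_equal(mcc(confusion_matrix(lp$t, lp$p)), cov_mcc(lp$t, lp$p),
                 tolerance = 1e-12)
  }
  perfect <- confusion_matrix(rep(states3, 10), rep(states3, 10))
  expect_equal(mcc(perfect), 1)
  degenerate <- confusion_matrix(sample(rep(states3, 5)), rep("N2N3", 15))
  expect_equal(mcc(degenerate), 0)
})

test_that("MCC of independent labels is near zero and class-permutation invariant", {
  lp <- rand_labels(1e5, seed = 48)
  expect_lt(abs(mcc(confusion_matrix(lp$t, lp$p))), 0.05)

  lp2 <- rand_labels(400, seed = 49)
  cm <- unclass(confusion_matrix(lp2$t, lp2$p))
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    pm <- cm[perm, perm]
    class(pm) <- "confusion_matrix"
    expect_equal(mcc(pm), mcc(confusion_matrix(lp2$t, lp2$p)), tolerance = 1e-12)
    expect_equal(accuracy(pm), accuracy(confusion_matrix(lp2$t, lp2$p)))
  }
})

test_that("per-class recalls are row fractions, undefined on empty rows", {
  lp <- rand_labels(800, seed = 50)
  rec <- class_recalls(confusion_matrix(lp$t, lp$p))
  for (k in 1:3) {
    mine <- lp$t == states3[k]
    expect_equal(rec$recall[k], mean(lp$p[mine] == states3[k]))
  }
  no_wake <- confusion_matrix(rep("N1REM", 10), sample(rep(states3, c(2, 5, 3))))
  r <- class_recalls(no_wake)
  expect_true(is.na(r$recall[r$state == "WAKE"]))
  expect_false(is.na(r$recall[r$state == "N1REM"]))

  ident <- confusion_matrix(rep(states3, 4), rep(states3, 4))
  expect_equal(class_recalls(ident)$recall, rep(1, 3))
})

test_that("the pooled confusion matrix is the sum of per-recording matrices", {
  withr::with_seed(51, {
    parts <- lapply(1:5, function(i) {
      lp <- rand_labels(100, seed = 51 + i)
      confusion_matrix(lp$t, lp$p)
    })
    all_t <- unlist(lapply(1:5, function(i) rand_labels(100, seed = 51 + i)$t))
    all_p <- unlist(lapply(1:5, function(i) rand_labels(100, seed = 51 + i)$p))
    pooled <- confusion_matrix(all_t, all_p)
    expect_equal(unclass(Reduce(`+`, parts)), unclass(pooled), ignore_attr = TRUE)
  })
})

test_that("row percentages sum to 100 within rounding", {
  lp <- rand_labels(500, seed = 57)
  pct <- row_percentages(confusion_matrix(lp$t, lp$p))
  expect_equal(unname(rowSums(pct)), rep(100, 3), tolerance = 0.1)
})

test_that("cohort accounting totals states exactly", {
  h1 <- hypnogram(c("W", "W"))
  acc1 <- cohort_accounting(list(h1))
  expect_equal(acc1$total_epochs, 2)
  expect_equal(acc1$mean_epochs_per_recording, 2)
  expect_equal(acc1$counts$n_epochs[acc1$counts$state == "W"], 2L)

  withr::with_seed(58, {
    hs <- lapply(1:4, function(i) hypnogram(sample(c("W", "N1", "N2", "N3", "R"), 50, TRUE)))
    acc <- cohort_accounting(hs)
    expect_equal(acc$total_epochs, 200)
    expect_equal(sum(acc$counts$n_epochs), 200)
    pooled <- unlist(lapply(hs, function(h) as.character(h$label)))
    expect_equal(acc$counts$n_epochs,
                 as.integer(table(factor(pooled, levels = c("W", "N1", "N2", "N3", "R")))))
  })
})

test_that("fold summaries use type-7 quantiles of per-recording metrics", {
  same <- tibble::tibble(acc = rep(0.8, 5), mcc = rep(0.6, 5))
  fs <- fold_summary(same)
  expect_equal(fs$median, c(0.8, 0.6))
  expect_equal(fs$iqr, c(0, 0))

  three <- tibble::tibble(acc = c(0.6, 0.7, 0.8), mcc = c(0.5, 0.6, 0.7))
  expect_equal(fold_summary(three)$median, c(0.7, 0.6))

  withr::with_seed(59, {
    vals <- tibble::tibble(acc = runif(11), mcc = runif(11, -1, 1))
    fs <- fold_summary(vals)
    # oracle: sort-based linear interpolation at h = (n-1)p + 1
    q7 <- function(x, p) {
      x <- sort(x)
      h <- (length(x) - 1) * p + 1
      lo <- floor(h)
      x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
    }
    expect_equal(fs$median[1], q7(vals$acc, 0.5))
    expect_equal(fs$q25[2], q7(vals$mcc, 0.25))
    expect_equal(fs$q75[1], q7(vals$acc, 0.75))
  })
})
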