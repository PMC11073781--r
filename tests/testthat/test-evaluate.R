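test_that("confusion metrics reproduce hand-computed values", {
  perfect <- confusion_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  truth <- c(rep(1, 10), rep(0, 90))
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 88))
  m <- confusion_metrics(truth, pred)
  expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]), c(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$f1, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$ppv, 0.8)

  degen <- confusion_metrics(rep(0, 5), rep(0, 5))
  expect_equal(degen$accuracy, 1)
  expect_equal(degen$f1, 0)
  expect_true(degen$degenerate)

  expect_error(confusion_metrics(c(0, 1), c(0, 1, 1)), class = "fetalpeaks_shape_error")
})

test_that("ROC endpoints and the chance level behave correctly", {
  y <- c(rep(0, 50), rep(1, 50))
  sep <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  expect_equal(roc_auc(y, sep)$auc, 1)
  expect_equal(roc_auc(1 - y, sep)$auc, 0)

  set.seed(99)
  y2 <- rbinom(10000, 1, 0.3)
  p2 <- runif(10000)
  expect_lt(abs(roc_auc(y2, p2)$auc - 0.5), 0.02)

  expect_error(roc_auc(rep(1, 10), runif(10)),
               class = "fetalpeaks_degenerate_class_error")
})

test_that("AUC is invariant under strictly monotone posterior transforms", {
  set.seed(4)
  y <- rbinom(300, 1, 0.3)
  p <- plogis(rnorm(300) + y)
  a0 <- roc_auc(y, p)$auc
  expect_equal(roc_auc(y, p^3)$auc, a0)
  expect_equal(roc_auc(y, qlogis(p))$auc, a0)
})

test_that("Pearson correlation matches hand computation and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_r(x, rep(1, 4)), class = "fetalpeaks_degenerate_variance_error")
})

test_that("Bland-Altman bias and limits follow the 1.96-SD rule", {
  a <- c(1, 2, 3)
  ident <- bland_altman(a, a)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  off <- bland_altman(a, a + 2)
  expect_equal(off$bias, -2)
  expect_equal(off$loa_high - off$loa_low, 0)

  two <- bland_altman(c(0, 2), c(2, 0))
  expect_equal(two$bias, 0)
  expect_equal(two$sd_diff, 2.828, tolerance = 1e-3)
  expect_equal(two$loa_high, 5.544, tolerance = 1e-3)

  # antisymmetry: swapping the pair negates the bias, keeps the LoA width
  set.seed(6)
  u <- rnorm(20, 140, 5); v <- u + rnorm(20, -3, 2)
  ba1 <- bland_altman(u, v); ba2 <- bland_altman(v, u)
  expect_equal(ba1$bias, -ba2$bias)
  expect_equal(ba1$loa_high - ba1$loa_low, ba2$loa_high - ba2$loa_low)
  expect_true(ba1$loa_low <= ba1$bias && ba1$bias <= ba1$loa_high)

  expect_error(bland_altman(1, 2), class = "fetalpeaks_insufficient_data_error")
})

majority_pipeline <- function(train_frames, test_frames) {
  maj <- as.integer(mean(train_frames$info$label) >= 0.5)
  rep(maj, dim(test_frames$x)[1])
}

make_cv_frames <- function(n_per_subject = 60, subjects = 3, seed = 1) {
  set.seed(seed)
  n <- n_per_subject * subjects
  x <- array(rnorm(n * 8 * 2), c(n, 8, 2))
  info <- tibble::tibble(
    frame = seq_len(n),
    start = (seq_len(n) - 1L) * 8L + 1L,
    subject = rep(sprintf("S%02d", seq_len(subjects)), each = n_per_subject),
    label = rbinom(n, 1, 0.3)
  )
  structure(list(x = x, info = info, fs = 1000, frame_len = 8L),
            class = "frame_set")
}

test_that("k-fold folds partition the frames and are seed-stable", {
  f <- make_cv_frames()
  cv1 <- kfold_cv(f, k = 5, majority_pipeline, seed = 3)
  cv2 <- kfold_cv(f, k = 5, majority_pipeline, seed = 3)
  expect_identical(cv1$assignment, cv2$assignment)
  expect_identical(sort(unique(cv1$assignment)), 1:5)
  expect_identical(length(cv1$assignment), 180L)
  expect_identical(nrow(cv1$folds), 5L)
  # every subject contributes to every fold
  tab <- table(f$info$subject, cv1$assignment)
  expect_true(all(tab > 0))
  expect_error(kfold_cv(f, k = 500, majority_pipeline), class = "fetalpeaks_config_error")
})

test_that("leave-one-subject-out isolates each subject and matches the analytic baseline", {
  f <- make_cv_frames()
  res <- loso_cv(f, majority_pipeline, seed = 2)
  expect_identical(nrow(res$subjects), 3L)
  for (s in unique(f$info$subject)) {
    class0 <- mean(f$info$label[f$info$subject == s] == 0)
    expect_equal(res$subjects$accuracy[res$subjects$subject == s], class0)
  }
  expect_equal(res$mean_accuracy, mean(res$subjects$accuracy))
  expect_error(loso_cv(subset_1 <- structure(list(
    x = f$x[1:10, , , drop = FALSE], info = f$info[1:10, ],
    fs = 1000, frame_len = 8L), class = "frame_set"), majority_pipeline),
    class = "fetalpeaks_config_error")
})

test_that("stratified summaries average the matching rows only", {
  tbl <- reference_cohort()
  all_rows <- stratified_summary(tbl, list(all = ~ rep(TRUE, length(ga_weeks))),
                                 accuracy_pct)
  expect_equal(all_rows$mean, mean(tbl$accuracy_pct))
  expect_identical(all_rows$n, 26L)

  expect_warning(
    out <- stratified_summary(tbl, list(none = ~ ga_weeks > 99, late = ~ ga_weeks > 34),
                              accuracy_pct),
    "matched no rows")
  expect_identical(out$stratum, "late")
})

test_that("beat-level matching is one-to-one within the tolerance", {
  truth <- c(1000L, 1430L, 1860L)
  det <- c(1010L, 1425L, 3000L)
  m <- match_peaks(det, truth, fs = 1000, tol_ms = 50)
  expect_equal(unlist(m[c("tp", "fp", "fn")]), c(tp = 2, fp = 1, fn = 1))
  # two detections cannot claim one reference peak
  m2 <- match_peaks(c(1000L, 1010L), 1005L, fs = 1000, tol_ms = 50)
  expect_equal(m2$tp, 1)
})
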