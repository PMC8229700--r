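test_that("stratified folds partition items with balanced classes", {
  labels <- rep(sprintf("s%d", 1:5), each = 100)
  folds <- stratified_kfold(labels, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  for (f in folds) {
    expect_equal(unname(table(labels[f])), rep(10L, 5), ignore_attr = TRUE)
  }
  expect_identical(stratified_kfold(labels, 10, seed = 3), folds)
  expect_error(stratified_kfold(rep(c("a", "b"), c(5, 100)), 10), ">= k")
})

test_that("session split trains and tests on disjoint sessions", {
  segs <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 100),
    session_id = rep(rep(c("1", "2"), each = 50), 2)
  )
  sp <- multisession_split(segs, seed = 1)
  expect_length(sp, 2)
  for (s in sp) {
    expect_length(intersect(s$train, s$test), 0)
    expect_equal(sort(c(s$train, s$test)), 1:200)
    expect_equal(length(s$train), 100)
  }
  # fold 2 swaps the roles of fold 1
  expect_equal(sort(sp[[1]]$train), sort(sp[[2]]$test))
  # single-session subject: seeded random halving
  one <- tibble::tibble(subject_id = "c", session_id = "1")[rep(1, 40), ]
  sp1 <- multisession_split(one, seed = 9)
  expect_equal(length(sp1[[1]]$train), 20)
  expect_identical(multisession_split(one, seed = 9), sp1)
})

test_that("accuracy follows (TP + TN) / total", {
  expect_equal(accuracy(confusion_counts(95, 0, 5, 0)), 0.95)
  expect_equal(accuracy(confusion_counts(50, 50, 0, 0)), 1.0)
  expect_equal(accuracy(confusion_counts(25, 25, 25, 25)), 0.5)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "Zero")
})

test_that("one-vs-rest collapse matches the hand-counted example", {
  cm <- matrix(c(8, 1, 1,
                 0, 10, 0,
                 2, 0, 8), nrow = 3, byrow = TRUE)
  cc <- one_vs_rest_counts(cm, 1)
  expect_equal(cc$tp, 8)
  expect_equal(cc$fn, 2)
  expect_equal(cc$fp, 2)
  expect_equal(cc$tn, 18)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, sum(cm))
  # perfect classifier: no off-diagonal mass anywhere
  ident <- diag(c(5, 5, 5))
  for (t in 1:3) {
    cci <- one_vs_rest_counts(ident, t)
    expect_equal(cci$fp, 0)
    expect_equal(cci$fn, 0)
  }
  expect_error(one_vs_rest_counts(cm, 4), "range")
})

test_that("verification metrics satisfy their identities on the hand count", {
  m <- verification_metrics(confusion_counts(8, 18, 2, 2))
  expect_equal(m$frr, 0.2)
  expect_equal(m$far, 0.1)
  expect_equal(m$hter, 0.15)
  expect_equal(m$frr + m$tar, 1)
  expect_equal(m$far + m$trr, 1)
  # perfect verification
  p <- verification_metrics(confusion_counts(10, 90, 0, 0))
  expect_equal(p$hter, 0)
  expect_error(verification_metrics(confusion_counts(0, 5, 5, 0)), "genuine")
})

test_that("HTER arithmetic reproduces published verification operating points", {
  # printed (FRR, FAR, HTER) triples for five network classifiers
  ops <- tibble::tibble(
    frr = c(0.0008, 0.0006, 0.0009, 0.0014, 0.0015),
    far = c(0.0658, 0.0489, 0.0731, 0.1019, 0.1153),
    hter_printed = c(0.033, 0.025, 0.037, 0.052, 0.058)
  )
  expect_equal(round(hter(ops$frr, ops$far), 3), ops$hter_printed)
})

test_that("McNemar with continuity correction matches direct arithmetic", {
  m <- mcnemar_yates(10, 2)
  expect_equal(m$statistic, 49 / 12)
  expect_equal(m$p_value, pchisq(49 / 12, 1, lower.tail = FALSE))
  z <- mcnemar_yates(0, 0)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # the 95% reference critical value
  expect_equal(round(mcnemar_critical(0.05), 4), 3.8415)
})

test_that("Fisher-Z summary matches atanh/tanh arithmetic", {
  expect_equal(fisher_z_summary(c(0.9, 0.9, 0.9))$mean, 0.9)
  fz <- fisher_z_summary(c(0.8, 0.95))
  expect_equal(fz$mean, tanh((atanh(0.8) + atanh(0.95)) / 2))
  expect_equal(fz$mean, 0.898657, tolerance = 1e-6)
  # duplicating every value leaves the mean unchanged
  expect_equal(fisher_z_summary(rep(c(0.8, 0.95), 2))$mean, fz$mean)
  # perfect accuracies are clamped, not infinite
  expect_true(is.finite(fisher_z_summary(c(1, 1, 0.99))$mean))
})

test_that("cumulative accuracy distribution is a non-increasing step curve", {
  curve <- cumulative_accuracy_distribution(c(0.5, 1.0))
  f <- attr(curve, "fraction_at")
  expect_equal(f(0.75), 0.5)
  expect_equal(f(0), 1)
  expect_true(all(diff(curve$fraction) <= 0))
  all1 <- cumulative_accuracy_distribution(rep(1, 5))
  expect_true(all(all1$fraction == 1))
})

test_that("phase 3 recovers known error rates from a synthetic confusion", {
  # 3 subjects, 20 trials each, known per-class errors
  truth <- rep(c("a", "b", "c"), each = 20)
  pred <- truth
  pred[1:4] <- "b"      # subject a: accuracy 0.8
  pred[21:22] <- "c"    # subject b: accuracy 0.9
  res <- run_phase3(tibble::tibble(truth = truth, pred = pred))
  expect_equal(res$per_subject$accuracy, c(0.8, 0.9, 1.0),
               ignore_attr = TRUE)
  expect_equal(sum(res$confusion), 60)
  # pooled one-vs-rest counts: every error is one FN and one FP
  expect_equal(res$verification$fn, 6)
  expect_equal(res$verification$fp, 6)
  expect_equal(res$mcnemar$statistic, mcnemar_yates(6, 6)$statistic)
  expect_equal(res$identification$mean,
               fisher_z_summary(c(0.8, 0.9, 1.0))$mean)
})
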