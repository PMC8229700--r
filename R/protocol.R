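#' Stratified k-fold cross-validation splits
#'
#' Shuffles each class independently (seeded) and deals its items round-robin
#' into `k` folds, so per-class proportions differ by at most one item across
#' folds. Folds partition the full index set.
#'
#' @param labels Vector of class labels (one per item).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A list of `k` integer vectors of test indices.
#' @export
stratified_kfold <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("Every class needs >= k items (smallest has %d, k = %d).",
                  min(tab), k))
  }
  set.seed(as.integer(seed))
  folds <- vector("list", k)
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    f <- rep_len(seq_len(k), length(idx))
    for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
  }
  lapply(folds, sort)
}

#' Two-fold session-wise split
#'
#' Splits a segment table into the two folds of multisession evaluation:
#' fold 1 trains on each subject's first session (sorted order) and tests on
#' the others; fold 2 swaps the roles. A subject with a single session has
#' its segments randomly halved between the two groups (seeded), emulating
#' re-use of the same record for both sessions.
#'
#' @param segments A segment tibble with `subject_id` and `session_id`.
#' @param seed Integer seed for the single-session fallback.
#' @return A list of two lists, each with integer `train` and `test` index
#'   vectors.
#' @export
multisession_split <- function(segments, seed = 1) {
  set.seed(as.integer(seed))
  group_a <- logical(nrow(segments))
  for (s in unique(segments$subject_id)) {
    idx <- which(segments$subject_id == s)
    sess <- sort(unique(segments$session_id[idx]))
    if (length(sess) >= 2) {
      group_a[idx] <- segments$session_id[idx] == sess[1]
    } else {
      half <- sample(idx, length(idx) %/% 2)
      group_a[half] <- TRUE
    }
  }
  list(
    list(train = which(group_a), test = which(!group_a)),
    list(train = which(!group_a), test = which(group_a))
  )
}

#' Confusion counts for a binary decision
#'
#' @param tp,tn,fp,fn Nonnegative integers.
#' @return A tibble of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  out <- tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / total trials`.
#'
#' @param counts A [confusion_counts()] row.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total <= 0) abort("Zero trials.")
  (counts$tp + counts$tn) / total
}

#' Multiclass confusion matrix from labels
#'
#' Rows are the true class, columns the predicted class.
#'
#' @param truth,pred Label vectors.
#' @param classes Optional class ordering.
#' @return A square integer matrix.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  classes <- classes %||% sort(unique(c(as.character(truth), as.character(pred))))
  m <- table(factor(truth, classes), factor(pred, classes))
  unclass(as.matrix(m))
}

#' One-vs-rest counts from a multiclass confusion matrix
#'
#' Collapses a multiclass confusion matrix (rows = truth, columns =
#' predicted) into the binary genuine/imposter counts for one target class:
#' `TP` the diagonal entry, `FN` the rest of the target row, `FP` the rest of
#' the target column, `TN` the remainder.
#'
#' @param cm Square confusion matrix.
#' @param target Class index or name.
#' @return A [confusion_counts()] row.
#' @export
one_vs_rest_counts <- function(cm, target) {
  if (nrow(cm) != ncol(cm)) abort("Confusion matrix must be square.")
  if (is.character(target)) target <- match(target, rownames(cm))
  if (is.na(target) || target < 1 || target > nrow(cm)) {
    abort("`target` is out of range.")
  }
  tp <- cm[target, target]
  fn <- sum(cm[target, ]) - tp
  fp <- sum(cm[, target]) - tp
  tn <- sum(cm) - tp - fn - fp
  confusion_counts(tp, tn, fp, fn)
}

#' Verification metrics from binary counts
#'
#' False rejection rate `FRR = FN / (FN + TP)`, false acceptance rate
#' `FAR = FP / (FP + TN)`, true acceptance rate `TAR = TP / (TP + FN)`,
#' true rejection rate `TRR = TN / (TN + FP)`, and the half total error rate
#' `HTER = (FRR + FAR) / 2`, which substitutes for the equal error rate when
#' scores are unavailable (decisions come from a classifier, not a
#' thresholded matcher).
#'
#' @param counts A [confusion_counts()] row.
#' @return A tibble with `frr`, `far`, `tar`, `trr`, `hter`.
#' @export
verification_metrics <- function(counts) {
  genuine <- counts$tp + counts$fn
  imposter <- counts$fp + counts$tn
  if (genuine <= 0) abort("No genuine attempts (TP + FN == 0).")
  if (imposter <= 0) abort("No imposter attempts (FP + TN == 0).")
  frr <- counts$fn / genuine
  far <- counts$fp / imposter
  tibble::tibble(frr = frr, far = far, tar = 1 - frr, trr = 1 - far,
                 hter = (frr + far) / 2)
}

#' Half total error rate from rates
#'
#' @param frr,far Error rates in `[0, 1]`.
#' @return `(FRR + FAR) / 2`.
#' @export
hter <- function(frr, far) (frr + far) / 2

#' McNemar test with continuity correction
#'
#' Chi-square statistic `(|b - c| - 1)^2 / (b + c)` on the two discordant
#' counts, 1 degree of freedom; the statistic is defined as 0 when
#' `b + c == 0`. For verification confusions the discordant pair is taken as
#' `b = FP`, `c = FN`.
#'
#' @param b,c Nonnegative discordant counts.
#' @return A tibble with `statistic`, `p_value`.
#' @export
mcnemar_yates <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1))
  }
  stat <- (abs(b - c) - 1)^2 / (b + c)
  tibble::tibble(statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Chi-square critical value for the McNemar test
#'
#' @param alpha Significance level (default 0.05).
#' @return The critical value of the chi-square distribution with 1 degree of
#'   freedom (3.8415 at alpha = 0.05).
#' @export
mcnemar_critical <- function(alpha = 0.05) qchisq(1 - alpha, df = 1)

#' Fisher-Z population summary of per-subject accuracies
#'
#' Accuracies are clamped to `[eps, 1 - eps]` (atanh diverges at 1, and
#' perfect per-subject accuracies do occur), transformed with `z = atanh(a)`,
#' summarized in z-space, and the mean is transformed back with `tanh`. The
#' standard deviation is reported both in z-space and as the half-width of
#' the back-transformed one-sd interval.
#'
#' @param accuracies Numeric vector in `[0, 1]`.
#' @param eps Clamping margin.
#' @return A tibble with `mean`, `sd_z`, `sd_backtransformed`.
#' @export
fisher_z_summary <- function(accuracies, eps = 1e-6) {
  if (!length(accuracies)) abort("`accuracies` must be nonempty.")
  a <- pmin(pmax(accuracies, eps), 1 - eps)
  z <- atanh(a)
  mz <- mean(z)
  sz <- if (length(z) > 1) sd(z) else 0
  tibble::tibble(
    mean = tanh(mz),
    sd_z = sz,
    sd_backtransformed = (tanh(mz + sz) - tanh(mz - sz)) / 2
  )
}

#' Cumulative accuracy distribution
#'
#' For each threshold, the fraction of subjects whose accuracy is at least
#' the threshold: a non-increasing step curve on `[0, 1]`.
#'
#' @param accuracies Numeric vector in `[0, 1]`.
#' @return A tibble with `threshold` and `fraction`, plus an attribute
#'   `fraction_at` (a function evaluating the curve at any threshold).
#' @export
cumulative_accuracy_distribution <- function(accuracies) {
  if (!length(accuracies)) abort("`accuracies` must be nonempty.")
  thr <- sort(unique(c(0, accuracies, 1)))
  frac <- vapply(thr, function(t) mean(accuracies >= t), numeric(1))
  out <- tibble::tibble(threshold = thr, fraction = frac)
  attr(out, "fraction_at") <- function(t) mean(accuracies >= t)
  class(out) <- c("cumulative_accuracy", class(out))
  out
}

#' @export
autoplot.cumulative_accuracy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold, .data$fraction)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "accuracy threshold",
                  y = "fraction of subjects at or above")
}
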