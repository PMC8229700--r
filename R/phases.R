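#' Build labelled scalogram images from records
#'
#' Full front end of the recognition pipeline for one (scheme, window)
#' choice: preprocess each record, detect fiducials where the scheme needs
#' them, cut segments, equalize lengths for the variable-length schemes,
#' top up (or seeded-subsample down to) `target_count` segments per group
#' with [augment_to_count()], and render CWT images.
#'
#' @param records Tibble with list-column `record` of [ecg_record()]s (e.g.
#'   from [synth_dataset()]).
#' @param scheme One of `"blind"`, `"r_centered"`, `"rr"`, `"pp"`.
#' @param window_s Window length in seconds (fixed-length schemes).
#' @param image_size Image side length in pixels.
#' @param target_count Segments per group after augmentation.
#' @param k Averaging count for synthetic segments.
#' @param seed Integer seed.
#' @param by Augmentation grouping (default per subject; use
#'   `c("subject_id", "session_id")` for session-disjoint augmentation).
#' @param low_hz,high_hz Preprocessing band.
#' @param ... Passed to [cwt_scalogram()] via [segments_to_images()].
#' @return A segment tibble with an `image` list-column.
#' @export
prepare_images <- function(records, scheme = "r_centered", window_s = 0.5,
                           image_size = 224, target_count = 100, k = 10,
                           seed = 1, by = "subject_id",
                           low_hz = 0.5, high_hz = 40, ...) {
  scheme <- match.arg(scheme, c("blind", "r_centered", "rr", "pp"))
  fs <- unique(vapply(records$record, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) abort("All records must share one sampling rate.")
  seg_list <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records$record[[i]]
    pre <- preprocess_ecg(rec, low_hz, high_hz)
    if (scheme == "blind") return(blind_segments(pre, window_s))
    r <- detect_r_peaks(pre)
    switch(scheme,
      r_centered = r_centered_segments(pre, r, window_s),
      rr = rr_segments(pre, r),
      pp = {
        p <- detect_p_peaks(rec, r)
        pp_segments(pre, p$p)
      })
  })
  segs <- dplyr::bind_rows(seg_list)
  if (!nrow(segs)) abort("No segments were produced.")
  if (scheme %in% c("rr", "pp")) segs <- resample_to_length(segs)
  # seeded subsample down when a group exceeds the target, then top up
  set.seed(as.integer(seed))
  key <- do.call(paste, c(unname(segs[by]), sep = "\r"))
  keep <- unlist(lapply(split(seq_len(nrow(segs)), key), function(ix) {
    if (length(ix) > target_count) sort(sample(ix, target_count)) else ix
  }), use.names = FALSE)
  segs <- segs[sort(keep), ]
  segs <- augment_to_count(segs, target_count = target_count, k = k,
                           seed = seed + 1L, by = by)
  segments_to_images(segs, fs = fs, size = image_size, ...)
}

evaluate_cv <- function(images, folds, config) {
  fold_rows <- vector("list", length(folds))
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(images)), test_idx)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_small_cnn(images[train_idx, ], config = cfg)
    pr <- predict(fit, images[test_idx, ])
    truth <- as.character(images$subject_id[test_idx])
    acc <- mean(pr$pred == truth)
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = length(test_idx),
                                     accuracy = acc)
    preds[[f]] <- tibble::tibble(fold = f, truth = truth, pred = pr$pred)
  }
  list(folds = dplyr::bind_rows(fold_rows),
       predictions = dplyr::bind_rows(preds))
}

evaluate_splits <- function(images, splits, config) {
  fold_rows <- vector("list", length(splits))
  preds <- vector("list", length(splits))
  for (f in seq_along(splits)) {
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_small_cnn(images[splits[[f]]$train, ], config = cfg)
    pr <- predict(fit, images[splits[[f]]$test, ])
    truth <- as.character(images$subject_id[splits[[f]]$test])
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = length(truth),
                                     accuracy = mean(pr$pred == truth))
    preds[[f]] <- tibble::tibble(fold = f, truth = truth, pred = pr$pred)
  }
  list(folds = dplyr::bind_rows(fold_rows),
       predictions = dplyr::bind_rows(preds))
}

#' Phase 1: segmentation scheme and window-length sweep
#'
#' For every (scheme, window) pair, builds images with [prepare_images()],
#' runs stratified k-fold cross-validation of the small CNN, and reports the
#' mean held-out accuracy. Reference window lists are 0.5-3 s for blind
#' segmentation and 0.5/0.75/1 s for R-centered segmentation; the R-R and
#' P-P schemes take one pseudo-window (`NA`).
#'
#' @param records Record tibble (see [prepare_images()]).
#' @param schemes Named list mapping scheme name to a vector of window
#'   lengths in seconds (`NA` for the variable-length schemes).
#' @param k_folds Number of cross-validation folds.
#' @param config A [train_config()].
#' @param image_size,target_count,seed Passed to [prepare_images()].
#' @param ... Passed on to [prepare_images()].
#' @return A tibble with `scheme`, `window_s`, `accuracy` (mean over folds)
#'   and a `folds` list-column of per-fold results.
#' @export
run_phase1 <- function(records,
                       schemes = list(blind = c(0.5, 1, 1.5, 2, 2.5, 3),
                                      r_centered = c(0.5, 0.75, 1),
                                      rr = NA, pp = NA),
                       k_folds = 10, config = train_config(),
                       image_size = 224, target_count = 100, seed = 1, ...) {
  rows <- list()
  for (scheme in names(schemes)) {
    for (w in schemes[[scheme]]) {
      images <- prepare_images(records, scheme = scheme, window_s = w,
                               image_size = image_size,
                               target_count = target_count, seed = seed, ...)
      folds <- stratified_kfold(images$subject_id, k_folds, seed = seed)
      res <- evaluate_cv(images, folds, config)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scheme = scheme, window_s = w,
        accuracy = mean(res$folds$accuracy), folds = list(res$folds))
    }
  }
  dplyr::bind_rows(rows)
}

#' Phase 2: single-, mixed- and multisession scenarios
#'
#' Evaluates the winning segment choice (R-centered, 0.5 s by default) in
#' three session scenarios: *single* (first session only, stratified k-fold),
#' *mixed* (sessions pooled before splitting, stratified k-fold) and *multi*
#' (2-fold session-wise split: train on one session group, test on the
#' other, swap, average). Subjects with a single session fall back to a
#' seeded random split of their segments in the multi scenario.
#'
#' @param records Record tibble covering one or more sessions per subject.
#' @param scheme,window_s Segment choice.
#' @param scenarios Subset of `c("single", "mixed", "multi")`.
#' @param k_folds Folds for the single/mixed scenarios.
#' @inheritParams run_phase1
#' @return A tibble with `scenario`, `accuracy`, `folds` and `predictions`
#'   list-columns (predictions carry truth/pred pairs for phase 3).
#' @export
run_phase2 <- function(records, scheme = "r_centered", window_s = 0.5,
                       scenarios = c("single", "mixed", "multi"),
                       k_folds = 10, config = train_config(),
                       image_size = 224, target_count = 100, seed = 1, ...) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  rows <- list()
  if (any(c("single", "mixed") %in% scenarios)) {
    pooled <- prepare_images(records, scheme = scheme, window_s = window_s,
                             image_size = image_size,
                             target_count = target_count, seed = seed,
                             by = "subject_id", ...)
  }
  if ("single" %in% scenarios) {
    first_sess <- records |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_min(.data$session_id, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    imgs <- prepare_images(first_sess, scheme = scheme, window_s = window_s,
                           image_size = image_size,
                           target_count = target_count, seed = seed,
                           by = "subject_id", ...)
    res <- evaluate_cv(imgs, stratified_kfold(imgs$subject_id, k_folds, seed),
                       config)
    rows$single <- tibble::tibble(scenario = "single",
                                  accuracy = mean(res$folds$accuracy),
                                  folds = list(res$folds),
                                  predictions = list(res$predictions))
  }
  if ("mixed" %in% scenarios) {
    res <- evaluate_cv(pooled,
                       stratified_kfold(pooled$subject_id, k_folds, seed),
                       config)
    rows$mixed <- tibble::tibble(scenario = "mixed",
                                 accuracy = mean(res$folds$accuracy),
                                 folds = list(res$folds),
                                 predictions = list(res$predictions))
  }
  if ("multi" %in% scenarios) {
    imgs <- prepare_images(records, scheme = scheme, window_s = window_s,
                           image_size = image_size,
                           target_count = target_count, seed = seed,
                           by = c("subject_id", "session_id"), ...)
    splits <- multisession_split(imgs, seed = seed)
    res <- evaluate_splits(imgs, splits, config)
    rows$multi <- tibble::tibble(scenario = "multi",
                                 accuracy = mean(res$folds$accuracy),
                                 folds = list(res$folds),
                                 predictions = list(res$predictions))
  }
  dplyr::bind_rows(rows)
}

#' Phase 3: identification and verification analysis
#'
#' Consumes truth/prediction pairs (normally the multisession predictions
#' from [run_phase2()]) and derives: the multiclass confusion matrix,
#' per-subject accuracies with their Fisher-Z population summary and
#' cumulative distribution (identification analysis), and pooled one-vs-rest
#' verification metrics with a McNemar continuity-corrected test on the
#' discordant counts `b = FP`, `c = FN` (verification analysis). No separate
#' verification model is trained; verification is derived from the
#' classifier's decisions.
#'
#' @param predictions Tibble with `truth` and `pred` character columns.
#' @return A list with `confusion` (matrix), `per_subject` (tibble),
#'   `identification` (Fisher-Z summary tibble), `cumulative` (curve tibble),
#'   `verification` (pooled metrics tibble), `mcnemar` (test tibble).
#' @export
run_phase3 <- function(predictions) {
  cm <- confusion_matrix(predictions$truth, predictions$pred)
  per_subject <- tibble::tibble(
    subject_id = rownames(cm),
    n = rowSums(cm),
    accuracy = ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)
  )
  pooled <- Reduce(function(a, b) confusion_counts(
    a$tp + b$tp, a$tn + b$tn, a$fp + b$fp, a$fn + b$fn),
    lapply(seq_len(nrow(cm)), function(i) one_vs_rest_counts(cm, i)))
  ver <- verification_metrics(pooled)
  list(
    confusion = cm,
    per_subject = per_subject,
    identification = fisher_z_summary(per_subject$accuracy),
    cumulative = cumulative_accuracy_distribution(per_subject$accuracy),
    verification = dplyr::bind_cols(pooled, ver),
    mcnemar = mcnemar_yates(pooled$fp, pooled$fn)
  )
}
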