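#' Heartbeat segmentation
#'
#' Four segment families are supported, mirroring how short ECG windows are
#' cut for recognition: fixed-duration windows taken blindly
#' ([blind_segments()]) or centred on each R-peak ([r_centered_segments()]),
#' and variable-length windows spanning consecutive fiducials
#' ([rr_segments()], [pp_segments()]). All functions return a *segment
#' table*: a tibble with one row per segment and columns
#' `subject_id`, `session_id`, `record_id`, `scheme`, `window_s`, `start`
#' (1-based index of the first sample) and the list-column `samples`.
#'
#' @param record An [ecg_record()].
#' @param window_s Window duration in seconds.
#' @param record_id Optional record label stored in the table.
#' @return A segment tibble (possibly with zero rows).
#' @name segmentation
NULL

new_segment_tbl <- function(record, scheme, window_s, starts, lengths,
                            record_id) {
  record_id <- record_id %||% paste0(record$subject_id, "_", record$session_id)
  samples <- purrr::map2(starts, lengths, function(s, l) {
    record$samples[s:(s + l - 1L)]
  })
  tibble::tibble(
    subject_id = record$subject_id,
    session_id = record$session_id,
    record_id = record_id,
    scheme = scheme,
    window_s = window_s,
    start = as.integer(starts),
    samples = samples
  )
}

empty_segment_tbl <- function() {
  tibble::tibble(
    subject_id = character(), session_id = character(),
    record_id = character(), scheme = character(), window_s = double(),
    start = integer(), samples = list()
  )
}

#' @rdname segmentation
#' @export
blind_segments <- function(record, window_s, record_id = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (window_s <= 0) abort("`window_s` must be positive.")
  w <- round(window_s * record$fs)
  k <- length(record$samples) %/% w
  if (k == 0) return(empty_segment_tbl())
  starts <- 1L + (seq_len(k) - 1L) * w
  new_segment_tbl(record, "blind", window_s, starts, rep(w, k), record_id)
}

#' @param r_peaks Integer vector of R-peak indices.
#' @rdname segmentation
#' @export
r_centered_segments <- function(record, r_peaks, window_s, record_id = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (!length(r_peaks)) abort("`r_peaks` must be nonempty.")
  n <- round(window_s * record$fs)
  starts <- as.integer(r_peaks) - n %/% 2L
  ok <- starts >= 1L & (starts + n - 1L) <= length(record$samples)
  if (!any(ok)) return(empty_segment_tbl())
  new_segment_tbl(record, "r_centered", window_s, starts[ok],
                  rep(n, sum(ok)), record_id)
}

interval_segments <- function(record, fiducials, scheme, record_id) {
  f <- sort(as.integer(fiducials))
  if (length(f) < 2) return(empty_segment_tbl())
  starts <- f[-length(f)]
  lengths <- diff(f)
  new_segment_tbl(record, scheme, NA_real_, starts, lengths, record_id)
}

#' @rdname segmentation
#' @export
rr_segments <- function(record, r_peaks, record_id = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  interval_segments(record, r_peaks, "rr", record_id)
}

#' @param p_peaks Integer vector of P-peak indices.
#' @rdname segmentation
#' @export
pp_segments <- function(record, p_peaks, record_id = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  interval_segments(record, p_peaks, "pp", record_id)
}

#' Resample segments to a common length
#'
#' Linear-interpolation resampling of every segment to `n_target` samples;
#' first and last samples are preserved exactly. Needed before imaging
#' variable-length (R-R, P-P) segments. With `n_target = NULL`, the median
#' original length is used.
#'
#' @param segments A segment tibble.
#' @param n_target Target length (>= 2), or `NULL` for the median length.
#' @return The segment tibble with resampled `samples`.
#' @export
resample_to_length <- function(segments, n_target = NULL) {
  lens <- lengths(segments$samples)
  if (any(lens < 2)) abort("All segments must have length >= 2.")
  n_target <- n_target %||% as.integer(round(stats::median(lens)))
  if (n_target < 2) abort("`n_target` must be >= 2.")
  segments$samples <- purrr::map(segments$samples, function(x) {
    if (length(x) == n_target) return(x)
    approx(seq_along(x), x, n = n_target)$y
  })
  segments
}

#' Top up each subject to a fixed segment count by averaging
#'
#' Augmentation by averaging: each subject (or each group given by `by`) is
#' topped up to `target_count` segments, where every synthetic segment is the
#' element-wise mean of `k` originals sampled with replacement from the same
#' group. Originals are never altered or discarded; synthetic rows carry
#' `synthetic = TRUE` and the indices of their source rows (within the group)
#' in the `sources` list-column.
#'
#' @param segments A segment tibble with equal-length samples.
#' @param target_count Segments per group after augmentation (default 100).
#' @param k Number of originals averaged per synthetic segment (default 10).
#' @param seed Integer seed; deterministic.
#' @param by Grouping columns (default `"subject_id"`).
#' @return The augmented segment tibble.
#' @export
augment_to_count <- function(segments, target_count = 100, k = 10, seed = 1,
                             by = "subject_id") {
  if (k < 1) abort("`k` must be >= 1.")
  lens <- unique(lengths(segments$samples))
  if (length(lens) > 1) abort("All segments must have equal length; resample first.")
  if (!"synthetic" %in% names(segments)) segments$synthetic <- FALSE
  if (!"sources" %in% names(segments)) {
    segments$sources <- vector("list", nrow(segments))
  }
  key <- do.call(paste, c(unname(segments[by]), sep = "\r"))
  groups <- sort(unique(key))
  set.seed(as.integer(seed))
  extra <- list()
  for (g in groups) {
    idx <- which(key == g)
    n <- length(idx)
    if (n == 0) abort(sprintf("Group '%s' has no segments.", g))
    if (n >= target_count) next
    deficit <- target_count - n
    mat <- do.call(rbind, segments$samples[idx])
    rows <- vector("list", deficit)
    for (j in seq_len(deficit)) {
      src <- sample.int(n, k, replace = TRUE)
      tmpl <- segments[idx[1], ]
      tmpl$samples <- list(colMeans(mat[src, , drop = FALSE]))
      tmpl$start <- NA_integer_
      tmpl$synthetic <- TRUE
      tmpl$sources <- list(as.integer(src))
      rows[[j]] <- tmpl
    }
    extra[[g]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(segments, dplyr::bind_rows(extra))
  counts <- table(do.call(paste, c(unname(out[by]), sep = "\r")))
  attr(out, "per_group_counts") <- counts
  out
}

#' Per-subject segment counts
#'
#' @param segments A segment tibble.
#' @return A tibble `subject_id`, `n`.
#' @export
segment_counts <- function(segments) {
  dplyr::count(segments, .data$subject_id, name = "n")
}
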