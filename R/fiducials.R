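#' Discrete curvature of a sampled signal
#'
#' Curvature proxy used for R-peak candidate generation: the second difference
#' of the signal after smoothing with a 10 ms moving average. Sharp convex
#' peaks (the R apex) map to strong local minima of the output; a straight
#' line maps to zero. The output has the same length as the input (the two
#' end samples are padded with 0).
#'
#' @param samples Numeric vector (length >= 3).
#' @param fs Sampling rate in Hz (sets the 10 ms smoothing width).
#' @return Numeric vector of curvatures, same length as `samples`.
#' @export
curvature <- function(samples, fs) {
  if (length(samples) < 3) abort("`samples` must have length >= 3.")
  sm <- moving_average(samples, round(0.01 * fs))
  d2 <- diff(sm, differences = 2)
  c(0, d2, 0)
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  idx <- which(x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  idx
}

#' Detect R-peaks
#'
#' Candidate R locations are local minima of the signal [curvature()] that
#' pass an adaptive threshold — the 0.98 quantile of `|curvature|` computed
#' over consecutive sliding windows (default 2 s). Each candidate is then
#' refined by a search-back: the final R index is the argmax of the
#' (preprocessed) signal within +/- 50 ms of the candidate. Candidates closer
#' than the refractory interval are resolved by keeping the one with the
#' larger signal amplitude.
#'
#' @param record A (preprocessed) [ecg_record()].
#' @param window_s Adaptive-threshold window in seconds.
#' @param refractory_s Minimum separation between detected R-peaks.
#' @param threshold_quantile Quantile of `|curvature|` a candidate must reach
#'   inside its window.
#' @param search_back_s Half-width of the search-back window.
#' @return Integer vector of strictly increasing R-peak sample indices.
#' @export
detect_r_peaks <- function(record, window_s = 2, refractory_s = 0.25,
                           threshold_quantile = 0.98, search_back_s = 0.05) {
  stopifnot(inherits(record, "ecg_record"))
  if (window_s < refractory_s || refractory_s <= 0) {
    abort("Need window_s >= refractory_s > 0.")
  }
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  w <- round(window_s * fs)
  if (n < w) {
    warn("Record shorter than one threshold window; no R-peaks detected.")
    return(integer())
  }
  cv <- curvature(x, fs)
  mins <- local_minima(cv)
  cand <- integer()
  starts <- seq(1L, n, by = w)
  for (s in starts) {
    e <- min(n, s + w - 1L)
    if (e - s < round(0.25 * fs)) next  # ignore tiny trailing remainder
    thr <- quantile(abs(cv[s:e]), threshold_quantile, names = FALSE)
    if (!is.finite(thr) || thr <= .Machine$double.eps) next
    m <- mins[mins >= s & mins <= e]
    cand <- c(cand, m[cv[m] <= -thr])
  }
  if (!length(cand)) return(integer())
  # search back in the signal for the true apex
  sb <- round(search_back_s * fs)
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, as.integer(i - sb)); hi <- min(n, as.integer(i + sb))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory suppression: keep the stronger of two close peaks
  refr <- round(refractory_s * fs)
  keep <- integer()
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < refr) {
      if (x[p] > x[keep[length(keep)]]) keep[length(keep)] <- p
    } else {
      keep <- c(keep, p)
    }
  }
  keep
}

#' Detect P-peaks to the left of known R-peaks
#'
#' For each R-peak with a full 245 ms left context, an approximate P location
#' is the argmax of a Hilbert (analytic-signal) envelope within the window
#' `[r - round(0.245 fs), r - round(guard_s fs))`; it is then refined by a
#' search-back in the preprocessed signal, analogous to the R-peak
#' search-back. The envelope signal is built to isolate P-wave energy: the
#' record is band-passed to `band`, the QRS region (+/- `mask_s` around each
#' R) is bridged by linear interpolation so QRS energy cannot leak into the
#' window, the local baseline is removed with a `detrend_s` moving average,
#' and the analytic-signal magnitude is taken. A guard of `guard_s` before R
#' (wider than the QRS bridge) keeps bridge-edge artefacts out of the search.
#' R-peaks without full left context yield no P.
#'
#' @param record A raw [ecg_record()] (the band-passing is done internally).
#' @param r_peaks Integer vector of R-peak indices.
#' @param window_s P search window before R (seconds).
#' @param guard_s Guard interval just before R excluded from the search.
#' @param mask_s Half-width of the QRS bridge around each R.
#' @param band Band-pass edges (Hz) for the envelope signal.
#' @param detrend_s Moving-average width for baseline removal.
#' @param refine_s Half-width of the signal search-back around the envelope
#'   candidate.
#' @return A tibble with columns `r` and `p` (sample indices), one row per
#'   R-peak that received a P.
#' @export
detect_p_peaks <- function(record, r_peaks, window_s = 0.245, guard_s = 0.13,
                           mask_s = 0.10, band = c(0.5, 10),
                           detrend_s = 0.25, refine_s = 0.05) {
  stopifnot(inherits(record, "ecg_record"))
  if (!length(r_peaks)) abort("`r_peaks` must be nonempty.")
  r_peaks <- as.integer(r_peaks)
  fs <- record$fs
  n <- length(record$samples)
  y <- bandpass_zerophase(record$samples, fs, band[1], band[2], order = 2)
  mask <- as.integer(round(mask_s * fs))
  for (r in r_peaks) {
    lo <- max(1L, r - mask); hi <- min(n, r + mask)
    y[lo:hi] <- seq(y[lo], y[hi], length.out = hi - lo + 1L)
  }
  y <- y - moving_average(y, round(detrend_s * fs))
  env <- hilbert_envelope(y)
  guard <- as.integer(round(guard_s * fs))
  for (r in r_peaks) {
    lo <- max(1L, r - guard); hi <- min(n, r + guard)
    env[lo:hi] <- -Inf
  }
  # smoothed preprocessed signal for the search-back refinement
  xs <- moving_average(preprocess_ecg(record)$samples, round(0.02 * fs))
  win <- as.integer(round(window_s * fs))
  ref <- as.integer(round(refine_s * fs))
  out_r <- integer(); out_p <- integer()
  for (r in r_peaks) {
    lo <- r - win
    hi <- r - guard - 1L
    if (lo < 1L || hi < lo) next
    seg <- env[lo:hi]
    if (all(!is.finite(seg))) next
    cand <- lo + which.max(seg) - 1L
    rlo <- max(lo, cand - ref); rhi <- min(hi, cand + ref)
    p <- rlo + which.max(xs[rlo:rhi]) - 1L
    out_r <- c(out_r, r); out_p <- c(out_p, p)
  }
  tibble::tibble(r = out_r, p = out_p)
}

#' Detect all fiducials of a record
#'
#' Convenience wrapper: band-pass preprocessing, R-peak detection on the
#' filtered trace, then P-peak detection.
#'
#' @param record An [ecg_record()].
#' @param low_hz,high_hz Preprocessing band (see [preprocess_ecg()]).
#' @param ... Passed to [detect_r_peaks()].
#' @return A list with elements `r` (integer indices) and `p` (tibble from
#'   [detect_p_peaks()]), plus the preprocessed record as `record`.
#' @export
detect_fiducials <- function(record, low_hz = 0.5, high_hz = 40, ...) {
  pre <- preprocess_ecg(record, low_hz, high_hz)
  r <- detect_r_peaks(pre, ...)
  p <- if (length(r)) detect_p_peaks(record, r) else tibble::tibble(r = integer(), p = integer())
  list(record = pre, r = r, p = p)
}

#' Score detected fiducials against ground truth
#'
#' Matches detections to truth greedily within a tolerance and reports
#' sensitivity (fraction of truth recovered) and positive predictivity
#' (fraction of detections that are true).
#'
#' @param detected,truth Integer index vectors.
#' @param fs Sampling rate in Hz.
#' @param tol_s Matching tolerance in seconds.
#' @return A tibble with `n_truth`, `n_detected`, `true_positive`,
#'   `sensitivity`, `ppv`.
#' @export
score_fiducials <- function(detected, truth, fs, tol_s = 0.010) {
  tol <- round(tol_s * fs)
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    d <- which(!used & abs(detected - t) <= tol)
    if (length(d)) {
      used[d[which.min(abs(detected[d] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  tibble::tibble(
    n_truth = length(truth),
    n_detected = length(detected),
    true_positive = tp,
    sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    ppv = if (length(detected)) tp / length(detected) else NA_real_
  )
}

#' Write fiducials as a two-column text file
#'
#' @param r,p Integer index vectors (P may be empty).
#' @param path Output path. Columns are `type` (`"R"`/`"P"`) and
#'   `sample_index`.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(r, p = integer(), path) {
  df <- rbind(
    data.frame(type = rep("R", length(r)), sample_index = as.integer(r)),
    data.frame(type = rep("P", length(p)), sample_index = as.integer(p))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
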