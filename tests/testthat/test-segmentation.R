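test_that("blind segmentation cuts non-overlapping windows and drops the tail", {
  rec <- ecg_record(sin(1:10000 / 7), 500)  # 20 s at 500 Hz
  s2 <- blind_segments(rec, 2)
  expect_equal(nrow(s2), 10)
  expect_true(all(lengths(s2$samples) == 1000))
  expect_equal(s2$start, 1L + 0:9 * 1000L)
  s3 <- blind_segments(rec, 3)
  expect_equal(nrow(s3), 6)  # 2 s remainder dropped
  short <- ecg_record(sin(1:200 / 7), 500)  # 0.4 s record
  expect_equal(nrow(blind_segments(short, 0.5)), 0)
})

test_that("R-centered windows are centred and bounds-checked", {
  rec <- ecg_record(sin(1:20000 / 9), 1000)
  seg <- r_centered_segments(rec, r_peaks = 10001L, window_s = 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 9751L)          # [9751, 10250] around index 10001
  expect_equal(lengths(seg$samples), 500L)
  expect_equal(seg$samples[[1]], rec$samples[9751:10250])
  # window would start before the record: dropped
  expect_equal(nrow(r_centered_segments(rec, 100L, 0.5)), 0)
  # at 500 Hz a 0.5 s window is 250 samples
  rec5 <- ecg_record(sin(1:10000 / 9), 500)
  seg5 <- r_centered_segments(rec5, c(3000L, 5000L), 0.5)
  expect_true(all(lengths(seg5$samples) == 250L))
})

test_that("fiducial-interval segments telescope", {
  rec <- ecg_record(sin(1:5000 / 9), 500)
  rr <- rr_segments(rec, c(500L, 1500L, 2400L))
  expect_equal(nrow(rr), 2)
  expect_equal(lengths(rr$samples), c(1000L, 900L))
  expect_equal(sum(lengths(rr$samples)), 2400L - 500L)
  expect_equal(nrow(rr_segments(rec, 500L)), 0)
  pp <- pp_segments(rec, c(100L, 300L))
  expect_equal(lengths(pp$samples), 200L)
})

test_that("length resampling preserves endpoints and linear ramps", {
  rec <- ecg_record(seq(0, 1, length.out = 900), 500)
  seg <- rr_segments(rec, c(1L, 900L))
  out <- resample_to_length(seg, 500)
  y <- out$samples[[1]]
  expect_length(y, 500)
  expect_equal(y[1], seg$samples[[1]][1])
  expect_equal(y[500], seg$samples[[1]][899])
  # a linear ramp stays a linear ramp under linear interpolation
  expect_lt(max(abs(y - seq(y[1], y[500], length.out = 500))), 1e-9)
  # identity when the target equals the current length
  same <- resample_to_length(seg, 899)
  expect_identical(same$samples[[1]], seg$samples[[1]])
})

test_that("averaging augmentation tops groups up to the target exactly", {
  rec <- clean_record(seed = 4, duration_s = 40)
  pre <- preprocess_ecg(rec)
  seg <- r_centered_segments(pre, detect_r_peaks(pre), 0.5)
  n0 <- nrow(seg)
  expect_gte(n0, 10)
  aug <- augment_to_count(seg, target_count = 100, k = 10, seed = 7)
  expect_equal(nrow(aug), 100)
  expect_equal(sum(!aug$synthetic), n0)
  # originals are untouched
  expect_identical(aug$samples[seq_len(n0)], seg$samples)
  # provenance reproduces each synthetic segment exactly
  mat <- do.call(rbind, seg$samples)
  for (i in which(aug$synthetic)[1:5]) {
    src <- aug$sources[[i]]
    expect_length(src, 10)
    expect_equal(aug$samples[[i]], colMeans(mat[src, , drop = FALSE]))
  }
  # determinism
  aug2 <- augment_to_count(seg, target_count = 100, k = 10, seed = 7)
  expect_identical(aug$samples, aug2$samples)
})

test_that("averaging identical originals reproduces the original", {
  seg <- tibble::tibble(
    subject_id = "a", session_id = "1", record_id = "a_1", scheme = "blind",
    window_s = 0.5, start = c(1L, 101L),
    samples = list(rep(2, 100), rep(2, 100))
  )
  aug <- augment_to_count(seg, target_count = 5, k = 10, seed = 1)
  expect_equal(nrow(aug), 5)
  for (i in 3:5) expect_equal(aug$samples[[i]], rep(2, 100))
})

test_that("augmentation requires equal lengths and nonempty groups", {
  seg <- tibble::tibble(
    subject_id = c("a", "a"), session_id = "1", record_id = "a_1",
    scheme = "rr", window_s = NA_real_, start = c(1L, 51L),
    samples = list(rep(1, 50), rep(1, 60))
  )
  expect_error(augment_to_count(seg, 10), "equal length")
})
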