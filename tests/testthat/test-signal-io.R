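test_that("ecg_record validates its invariants", {
  expect_error(ecg_record(numeric(0), 500), "nonempty")
  expect_error(ecg_record(c(1, NA), 500), "non-finite")
  expect_error(ecg_record(1:10, -1), "positive")
  expect_error(ecg_record(1:10, 500, truth_fiducials = list(r = 11L)),
               "outside")
  rec <- ecg_record(sin(1:5000 / 50), 500)
  expect_s3_class(rec, "ecg_record")
  expect_equal(length(rec), 5000)
})

test_that("CSV round trip preserves the signal and parses identity", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(round(sin(1:5000 / 30), 6), 1000,
                    subject_id = "S007", session_id = "2")
  path <- file.path(dir, "S007_2.csv")
  write_ecg_csv(rec, path)
  back <- read_ecg_csv(path, fs = 1000)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_equal(back$subject_id, "S007")
  expect_equal(back$session_id, "2")
  # a 5000-value file at 1 kHz is a 5 s record
  expect_equal(length(back) / back$fs, 5)
})

test_that("CSV reader errors usefully", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("0.1", "0.2", "NaN", "0.4"), bad)
  expect_error(read_ecg_csv(bad, 500), "row 3")
  empty <- file.path(dir, "empty.csv")
  writeLines(character(), empty)
  expect_error(read_ecg_csv(empty, 500), "empty")
  expect_error(read_ecg_csv(file.path(dir, "absent.csv"), 500), "not found")
  # header line is skipped when flagged
  withhead <- file.path(dir, "h.csv")
  writeLines(c("amplitude", "1", "2"), withhead)
  expect_equal(read_ecg_csv(withhead, 500, header = TRUE)$samples, c(1, 2))
})

test_that("WFDB round trip recovers one lead of a multi-lead record", {
  dir <- withr::local_tempdir()
  fs <- 500
  n <- fs * 20
  lead_i <- round(sin((1:n) / 40), 3)
  lead_ii <- round(cos((1:n) / 40), 3)
  # write a two-signal format-16 record by hand
  writeLines(c(
    sprintf("S012_1 2 %d %d", fs, n),
    "S012_1.dat 16 1000(0)/mV 16 0 0 0 0 i",
    "S012_1.dat 16 1000(0)/mV 16 0 0 0 0 ii"
  ), file.path(dir, "S012_1.hea"))
  inter <- as.integer(round(rbind(lead_i, lead_ii) * 1000))
  writeBin(as.vector(inter), file.path(dir, "S012_1.dat"),
           size = 2, endian = "little")
  rec <- read_wfdb(file.path(dir, "S012_1"), lead = "i")
  # a 20 s record at 500 Hz has 10,000 samples
  expect_equal(length(rec), 10000)
  expect_equal(rec$samples, lead_i, tolerance = 1e-6)
  expect_equal(rec$subject_id, "S012")
  expect_equal(rec$session_id, "1")
  expect_error(read_wfdb(file.path(dir, "S012_1"), lead = "v5"), "not found")
  expect_error(read_wfdb(file.path(dir, "nothere")), "not found")
  # package writer round-trips through the reader
  out <- write_wfdb(rec, dir, record_name = "S012_2")
  back <- read_wfdb(sub("\\.hea$", "", out), lead = "i")
  expect_equal(back$samples, rec$samples, tolerance = 1e-3)
})

test_that("manifest overrides filename identity parsing", {
  dir <- withr::local_tempdir()
  man_path <- file.path(dir, "manifest.tsv")
  writeLines(c("record\tsubject_id\tsession_id", "rec99\talice\t3"), man_path)
  man <- read_manifest(man_path)
  writeLines(c("0.5", "0.7"), file.path(dir, "rec99.csv"))
  rec <- read_ecg_csv(file.path(dir, "rec99.csv"), 250, manifest = man)
  expect_equal(rec$subject_id, "alice")
  expect_equal(rec$session_id, "3")
})

test_that("preprocessing removes DC, keeps passband content, and is zero-phase", {
  fs <- 500
  rec <- ecg_record(rep(2.5, 4000), fs)
  out <- preprocess_ecg(rec, 0.5, 40)
  expect_lt(max(abs(out$samples)), 1e-6)

  # 1 Hz + 25 Hz sum: both retained, checked on the DFT amplitude spectrum
  t <- (0:(fs * 8 - 1)) / fs
  x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 25 * t)
  filt <- preprocess_ecg(ecg_record(x, fs), 0.5, 40)$samples
  amp <- function(sig, f) {
    n <- length(sig)
    2 * Mod(fft(sig)[f * n / fs + 1]) / n
  }
  expect_equal(amp(filt, 1), amp(x, 1), tolerance = 0.05)
  expect_equal(amp(filt, 25), amp(x, 25), tolerance = 0.05)

  # R apexes do not shift
  rec2 <- clean_record(seed = 5)
  pre <- preprocess_ecg(rec2)
  for (r in rec2$truth_fiducials$r[2:5]) {
    win <- (r - 10):(r + 10)
    expect_equal(win[which.max(pre$samples[win])],
                 win[which.max(rec2$samples[win])])
  }

  expect_error(preprocess_ecg(rec, 10, 5), "low_hz")
  expect_error(preprocess_ecg(rec, 0.5, 300), "Nyquist")
})

test_that("preprocessing is idempotent well inside the passband", {
  # mid-band tone, asserted away from the edges: the 0.5 Hz high-pass has a
  # multi-second impulse-response tail, and near either band edge the squared
  # response deviates from the single response by (f/fc)^(2*order)
  fs <- 500
  t <- (0:(fs * 30 - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  once <- preprocess_ecg(ecg_record(x, fs))
  twice <- preprocess_ecg(once)
  rng <- diff(range(once$samples))
  mid <- (10 * fs):(length(x) - 10 * fs)
  expect_lt(max(abs(once$samples[mid] - twice$samples[mid])) / rng, 1e-6)
})

test_that("resampling preserves duration, fiducials and band-limited content", {
  rec <- ecg_record(sin(2 * pi * 5 * (0:9999) / 1000), 1000,
                    truth_fiducials = list(r = c(1000L, 2000L)))
  down <- resample_record(rec, 500)
  expect_equal(length(down), 5000)
  expect_equal(down$fs, 500)
  # index 1000 (1-based, 1 kHz) is time 0.999 s -> sample 500.5 -> 500/501
  expect_equal(down$truth_fiducials$r, c(501L, 1001L), tolerance = 1)
  expect_identical(resample_record(rec, 1000), rec)
  # round trip reconstructs a band-limited signal
  back <- resample_record(down, 1000)
  expect_equal(length(back), 10000)
  mid <- 100:9900
  expect_lt(max(abs(back$samples[mid] - rec$samples[mid])), 0.01)
})
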