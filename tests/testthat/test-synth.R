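test_that("population sampling is deterministic and respects invariants", {
  a <- sample_population(90, seed = 11)
  b <- sample_population(90, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 90)
  expect_equal(anyDuplicated(a$a_r), 0)
  c <- sample_population(90, seed = 12)
  expect_false(isTRUE(all.equal(a$a_r, c$a_r)))
  # wave ordering and overlap invariants
  expect_true(all(a$theta_p < a$theta_q & a$theta_q < 0))
  expect_true(all(a$theta_s > 0 & a$theta_t > a$theta_s))
  expect_true(all(-a$theta_p <= 0.245))
  expect_true(all(a$mean_rr > 2 * (a$theta_t - a$theta_p)))
  expect_error(sample_population(0), ">= 1")
})

test_that("synthesized records put a local maximum at every truth R", {
  pop <- clean_population(3, seed = 21)
  for (i in 1:3) {
    rec <- synthesize_record(pop[i, ], duration_s = 20, fs = 500, seed = i)
    for (r in rec$truth_fiducials$r) {
      lo <- max(1, r - 2); hi <- min(length(rec), r + 2)
      expect_equal(which.max(rec$samples[(r - 10):(r + 10)]) + r - 11 - r,
                   0, tolerance = 2)
    }
    # P truth always within 245 ms before R
    expect_true(all(rec$truth_fiducials$r - rec$truth_fiducials$p <=
                      round(0.245 * rec$fs)))
    expect_true(all(rec$truth_fiducials$p < rec$truth_fiducials$r))
  }
})

test_that("beat count matches the RR interval for jitter-free records", {
  pop <- clean_population(2, seed = 8)
  pop$mean_rr[1] <- 1.0
  pop$rr_jitter_sd[1] <- 0
  rec <- synthesize_record(pop[1, ], duration_s = 20, fs = 500, seed = 1)
  # one beat per second over 20 s, minus edge placement: 19 or 20 beats
  expect_true(length(rec$truth_fiducials$r) %in% c(19L, 20L))
  expect_lt(max(diff(rec$truth_fiducials$r)) / rec$fs, 1.0 + 1e-9)
})

test_that("generation is deterministic and session drift preserves ordering", {
  pop <- sample_population(2, seed = 5)
  r1 <- synthesize_record(pop[1, ], seed = 9)
  r2 <- synthesize_record(pop[1, ], seed = 9)
  expect_identical(r1$samples, r2$samples)
  pert <- session_perturb(pop[1, ], seed = 4)
  expect_true(pert$theta_p < pert$theta_q && pert$theta_q < 0)
  expect_true(pert$theta_t > pert$theta_s && pert$theta_s > 0)
  expect_true(-pert$theta_p <= 0.245)
  # zero drift is the identity
  p0 <- pop[1, ]; p0$session_drift_sd <- 0
  expect_identical(session_perturb(p0, seed = 4), p0)
})

test_that("intra-subject beats correlate more than inter-subject beats", {
  pop <- sample_population(2, seed = 31)
  win <- function(rec) {
    n <- round(0.25 * rec$fs)
    rs <- rec$truth_fiducials$r
    rs <- rs[rs - n >= 1 & rs + n <= length(rec)]
    t(vapply(rs, function(r) rec$samples[(r - n):(r + n)], numeric(2 * n + 1)))
  }
  w1 <- win(synthesize_record(pop[1, ], seed = 1))
  w2 <- win(synthesize_record(pop[2, ], seed = 2))
  intra <- mean(cor(t(w1))[upper.tri(diag(nrow(w1)))])
  inter <- mean(cor(t(w1), t(w2)))
  expect_gt(intra, inter)
})

test_that("cross-session intra-subject correlation stays above inter-subject", {
  ds <- synth_dataset(2, n_sessions = 2, duration_s = 20, fs = 500, seed = 13)
  win <- function(rec) {
    n <- round(0.25 * rec$fs)
    rs <- rec$truth_fiducials$r
    rs <- rs[rs - n >= 1 & rs + n <= length(rec)]
    t(vapply(rs, function(r) rec$samples[(r - n):(r + n)], numeric(2 * n + 1)))
  }
  s1a <- win(ds$record[[1]]); s1b <- win(ds$record[[2]])
  s2a <- win(ds$record[[3]])
  intra_cross_session <- mean(cor(t(s1a), t(s1b)))
  inter <- mean(cor(t(s1a), t(s2a)))
  expect_gt(intra_cross_session, inter)
})

test_that("synthetic datasets export to disk with a manifest", {
  dir <- withr::local_tempdir()
  ds <- synth_dataset(2, n_sessions = 2, duration_s = 5, fs = 250, seed = 2)
  man <- write_synth_dataset(ds, dir)
  expect_true(file.exists(man))
  m <- read_manifest(man)
  expect_equal(nrow(m), 4)
  rec <- read_ecg_csv(file.path(dir, paste0(m$record[1], ".csv")),
                      fs = 250, manifest = m)
  expect_equal(rec$subject_id, ds$subject_id[1])
})
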