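#' Sample a synthetic ECG population
#'
#' Draws per-subject morphological parameter sets for the Gaussian-bump beat
#' model used by [synthesize_record()]. Each beat is a sum of five Gaussian
#' waves (P, Q, R, S, T), each with an amplitude `a_w` (mV), width `b_w` (s)
#' and time offset `theta_w` (s, R at 0). Parameters are drawn uniformly from
#' physiologically plausible ranges:
#'
#' * amplitudes: P 0.05-0.25, Q -0.2 to -0.05, R 0.8-1.6, S -0.35 to -0.1,
#'   T 0.1-0.5 mV
#' * widths: P 0.020-0.035, Q 0.008-0.015, R 0.008-0.016, S 0.010-0.020,
#'   T 0.040-0.070 s
#' * offsets: P -0.20 to -0.14, Q -0.045 to -0.025, S 0.025-0.050,
#'   T 0.16-0.24 s
#' * mean RR interval 0.7-1.1 s, floored at `2 * (theta_T - theta_P) + 0.05`
#'   so consecutive beats never overlap
#'
#' Session-invariant nuisance defaults: RR jitter sd 0.04 s, white noise sd
#' 0.05 mV, baseline wander 0.1 mV at 0.33 Hz, session amplitude drift sd 0.08
#' (relative).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; the draw is fully deterministic given the seed.
#' @param noise_sd,wander_amp,rr_jitter_sd,session_drift_sd Optional overrides
#'   of the nuisance defaults (applied to every subject).
#' @return A tibble with one row per subject: `subject_id` plus all model
#'   parameters (`a_p` ... `theta_t`, `mean_rr`, `rr_jitter_sd`, `noise_sd`,
#'   `wander_amp`, `wander_hz`, `session_drift_sd`).
#' @export
sample_population <- function(n_subjects, seed = 1,
                              noise_sd = 0.05, wander_amp = 0.1,
                              rr_jitter_sd = 0.04, session_drift_sd = 0.08) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be >= 1.")
  }
  n_subjects <- as.integer(n_subjects)
  set.seed(as.integer(seed))
  u <- function(lo, hi) runif(n_subjects, lo, hi)
  pop <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    a_p = u(0.05, 0.25),  b_p = u(0.020, 0.035), theta_p = u(-0.20, -0.14),
    a_q = u(-0.20, -0.05), b_q = u(0.008, 0.015), theta_q = u(-0.045, -0.025),
    a_r = u(0.8, 1.6),    b_r = u(0.008, 0.016), theta_r = 0,
    a_s = u(-0.35, -0.10), b_s = u(0.010, 0.020), theta_s = u(0.025, 0.050),
    a_t = u(0.10, 0.50),  b_t = u(0.040, 0.070), theta_t = u(0.16, 0.24),
    mean_rr = u(0.7, 1.1),
    rr_jitter_sd = rr_jitter_sd,
    noise_sd = noise_sd,
    wander_amp = wander_amp,
    wander_hz = 0.33,
    session_drift_sd = session_drift_sd
  )
  # keep the no-overlap invariant mean_rr > 2 * beat span
  span <- pop$theta_t - pop$theta_p
  pop$mean_rr <- pmax(pop$mean_rr, 2 * span + 0.05)
  validate_subject_params(pop)
  pop
}

validate_subject_params <- function(pop) {
  stopifnot(all(pop$b_p > 0), all(pop$b_q > 0), all(pop$b_r > 0),
            all(pop$b_s > 0), all(pop$b_t > 0))
  ok_order <- pop$theta_p < pop$theta_q & pop$theta_q < 0 &
    pop$theta_s > 0 & pop$theta_t > pop$theta_s
  if (!all(ok_order)) abort("Wave offsets must satisfy P < Q < R=0 < S < T.")
  if (!all(-pop$theta_p <= 0.245)) {
    abort("P offset must lie within 245 ms before R.")
  }
  if (!all(pop$mean_rr > 2 * (pop$theta_t - pop$theta_p))) {
    abort("mean_rr must exceed twice the beat span.")
  }
  invisible(pop)
}

#' Perturb subject parameters for a new acquisition session
#'
#' Emulates session-to-session drift: wave amplitudes are multiplied by
#' `1 + N(0, session_drift_sd)`, widths by `1 + N(0, session_drift_sd / 2)`,
#' and the P/T offsets are jittered by `N(0, 5 ms)`. Draws are repeated until
#' the wave-ordering invariants hold.
#'
#' @param params A one-row tibble (or a row) from [sample_population()].
#' @param seed Integer seed.
#' @return A perturbed one-row parameter tibble.
#' @export
session_perturb <- function(params, seed = 1) {
  stopifnot(nrow(params) == 1)
  sd_amp <- params$session_drift_sd
  if (sd_amp == 0) return(params)
  set.seed(as.integer(seed))
  for (try in 1:100) {
    out <- params
    for (w in c("p", "q", "r", "s", "t")) {
      a <- paste0("a_", w); b <- paste0("b_", w)
      out[[a]] <- params[[a]] * (1 + rnorm(1, 0, sd_amp))
      out[[b]] <- params[[b]] * abs(1 + rnorm(1, 0, sd_amp / 2))
    }
    out$theta_p <- params$theta_p + rnorm(1, 0, 0.005)
    out$theta_t <- params$theta_t + rnorm(1, 0, 0.005)
    ok <- out$theta_p < out$theta_q && out$theta_t > out$theta_s &&
      -out$theta_p <= 0.245 && out$a_r > 0 &&
      out$mean_rr > 2 * (out$theta_t - out$theta_p)
    if (ok) return(out)
  }
  params
}

#' Synthesize one ECG record
#'
#' Generates a single-lead trace in which every beat is the sum of five
#' Gaussian bumps `a_w * exp(-(t - t_beat - theta_w)^2 / (2 b_w^2))`. Beat
#' times follow `t_{k+1} = t_k + max(0.4, mean_rr + N(0, rr_jitter_sd))`.
#' White Gaussian noise (`noise_sd`) and one sinusoidal baseline-wander
#' component (`wander_amp`, `wander_hz`, random phase) are added. Ground-truth
#' R and P bump centres (rounded to the nearest sample) are stored in
#' `truth_fiducials`.
#'
#' @param params One-row parameter tibble from [sample_population()].
#' @param duration_s Record duration in seconds (> `mean_rr`).
#' @param fs Sampling rate in Hz (>= 100).
#' @param session_id Session label.
#' @param seed Integer seed; generation is deterministic given
#'   `(params, seed)`.
#' @return An [ecg_record()] with ground-truth fiducials.
#' @export
synthesize_record <- function(params, duration_s = 20, fs = 500,
                              session_id = "1", seed = 1) {
  stopifnot(nrow(params) == 1)
  if (duration_s <= params$mean_rr) abort("`duration_s` must exceed mean_rr.")
  if (fs < 100) abort("`fs` must be at least 100 Hz.")
  validate_subject_params(params)
  set.seed(as.integer(seed))
  # beat centres; first beat placed so its P wave is inside the record
  t_beat <- -params$theta_p + 0.05
  beats <- numeric(0)
  while (t_beat < duration_s) {
    beats <- c(beats, t_beat)
    t_beat <- t_beat + max(0.4, params$mean_rr + rnorm(1, 0, params$rr_jitter_sd))
  }
  # drop trailing beats whose T wave would be clipped
  beats <- beats[beats + params$theta_t + 3 * params$b_t < duration_s]
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (w in c("p", "q", "r", "s", "t")) {
    a <- params[[paste0("a_", w)]]
    b <- params[[paste0("b_", w)]]
    th <- params[[paste0("theta_", w)]]
    for (tb in beats) {
      ctr <- tb + th
      lo <- max(1L, floor((ctr - 5 * b) * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * b) * fs) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        x[idx] <- x[idx] + a * exp(-(t[idx] - ctr)^2 / (2 * b^2))
      }
    }
  }
  if (params$noise_sd > 0) x <- x + rnorm(n, 0, params$noise_sd)
  if (params$wander_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    x <- x + params$wander_amp * sin(2 * pi * params$wander_hz * t + phase)
  }
  r_idx <- as.integer(round(beats * fs)) + 1L
  p_idx <- as.integer(round((beats + params$theta_p) * fs)) + 1L
  keep <- r_idx >= 1 & r_idx <= n & p_idx >= 1
  ecg_record(x, fs,
             subject_id = params$subject_id, session_id = session_id,
             truth_fiducials = list(r = r_idx[keep], p = p_idx[keep]),
             meta = list(synthetic = TRUE, seed = seed))
}

#' Generate a multi-subject, multi-session synthetic dataset
#'
#' Draws a population with [sample_population()], perturbs each subject's
#' parameters per session with [session_perturb()], and synthesizes one record
#' per (subject, session).
#'
#' @inheritParams sample_population
#' @param n_sessions Sessions per subject.
#' @param duration_s,fs Passed to [synthesize_record()].
#' @param ... Passed to [sample_population()] (nuisance overrides).
#' @return A tibble with columns `subject_id`, `session_id` and a list-column
#'   `record` of [ecg_record()] objects.
#' @export
synth_dataset <- function(n_subjects, n_sessions = 1, duration_s = 20,
                          fs = 500, seed = 1, ...) {
  pop <- sample_population(n_subjects, seed = seed, ...)
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             session = seq_len(n_sessions))
  recs <- purrr::pmap(grid, function(subject, session) {
    p <- pop[subject, ]
    p_sess <- if (session == 1) p else {
      session_perturb(p, seed = seed + 7919L * session + subject)
    }
    synthesize_record(p_sess, duration_s = duration_s, fs = fs,
                      session_id = as.character(session),
                      seed = seed + 104729L * session + 13L * subject)
  })
  tibble::tibble(
    subject_id = pop$subject_id[grid$subject],
    session_id = as.character(grid$session),
    record = recs
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes each record as a one-column CSV (or WFDB pair) plus a manifest
#' mapping file stems to subject/session identity.
#'
#' @param dataset Tibble from [synth_dataset()].
#' @param dir Output directory.
#' @param format `"csv"` or `"wfdb"`.
#' @return The manifest path, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stems <- paste0(dataset$subject_id, "_", dataset$session_id)
  for (i in seq_len(nrow(dataset))) {
    if (format == "csv") {
      write_ecg_csv(dataset$record[[i]], file.path(dir, paste0(stems[i], ".csv")))
    } else {
      write_wfdb(dataset$record[[i]], dir, record_name = stems[i])
    }
  }
  man <- file.path(dir, "manifest.tsv")
  write.table(
    data.frame(record = stems, subject_id = dataset$subject_id,
               session_id = dataset$session_id),
    man, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(man)
}
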