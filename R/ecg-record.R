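#' Construct an ECG record
#'
#' An `ecg_record` holds one sampled single-lead ECG trace together with its
#' sampling rate, subject/session identity and (optionally) ground-truth
#' fiducial positions. It is the unit every downstream stage (filtering,
#' fiducial detection, segmentation) operates on.
#'
#' @param samples Numeric vector of amplitudes in millivolts. Must be nonempty
#'   and finite.
#' @param fs Sampling rate in Hz (positive).
#' @param subject_id,session_id Character identity labels.
#' @param lead Lead label (default `"i"`).
#' @param truth_fiducials Optional list with integer vectors `r` and `p`
#'   (1-based sample indices of true R- and P-wave centres).
#' @param meta Optional named list of annotations.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, subject_id = "unknown", session_id = "1",
                       lead = "i", truth_fiducials = NULL, meta = list()) {
  samples <- as.numeric(samples)
  stopifnot_scalar_number(fs, "fs")
  if (fs <= 0) abort("`fs` must be positive.")
  if (length(samples) == 0) abort("`samples` must be nonempty.")
  if (!all(is.finite(samples))) abort("`samples` contains non-finite values.")
  if (!is.null(truth_fiducials)) {
    idx <- unlist(truth_fiducials, use.names = FALSE)
    if (length(idx) && (any(idx < 1) || any(idx > length(samples)))) {
      abort("`truth_fiducials` indices fall outside the record.")
    }
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      session_id = as.character(session_id),
      lead = as.character(lead),
      fs = as.numeric(fs),
      samples = samples,
      truth_fiducials = truth_fiducials,
      meta = meta
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> subject %s, session %s, lead %s: %d samples @ %g Hz (%.2f s)\n",
    x$subject_id, x$session_id, x$lead, length(x$samples), x$fs,
    length(x$samples) / x$fs
  ))
  if (!is.null(x$truth_fiducials)) {
    cat(sprintf(
      "  truth fiducials: %d R, %d P\n",
      length(x$truth_fiducials$r %||% integer()),
      length(x$truth_fiducials$p %||% integer())
    ))
  }
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

parse_record_identity <- function(stem, manifest = NULL) {
  if (!is.null(manifest)) {
    hit <- manifest[manifest$record == stem, , drop = FALSE]
    if (nrow(hit) == 1) {
      return(list(subject_id = as.character(hit$subject_id[1]),
                  session_id = as.character(hit$session_id[1])))
    }
  }
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) >= 2) {
    list(subject_id = paste(parts[-length(parts)], collapse = "_"),
         session_id = parts[length(parts)])
  } else {
    list(subject_id = stem, session_id = "1")
  }
}

#' Read a record manifest
#'
#' A manifest is a tab- or comma-separated text file with columns `record`,
#' `subject_id` and `session_id`, mapping file stems to identities.
#'
#' @param path Path to the manifest file.
#' @return A tibble with columns `record`, `subject_id`, `session_id`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("record", "subject_id", "session_id")
  if (!all(need %in% names(df))) {
    abort(sprintf("Manifest %s must have columns: %s", path,
                  paste(need, collapse = ", ")))
  }
  tibble::as_tibble(df[need])
}

#' Read a WFDB record (text header + 16-bit signal file)
#'
#' Reads the PhysioNet WFDB format in its most common flavour: a plain-text
#' `.hea` header and an interleaved little-endian 16-bit `.dat` signal file
#' (format 16). One lead is extracted; the others are discarded. Subject and
#' session identity are parsed from the record stem using the
#' `<subject>_<session>` convention, or taken from `manifest` when given.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param lead Signal description (lead name) to extract, e.g. `"i"`.
#' @param manifest Optional manifest tibble from [read_manifest()].
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(path, lead = "i", manifest = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort(sprintf("Corrupt WFDB header (too short): %s", hea))
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) abort(sprintf("Corrupt WFDB header line 1: %s", hea))
  record_name <- top[1]
  n_sig <- suppressWarnings(as.integer(top[2]))
  fs <- suppressWarnings(as.numeric(top[3]))
  n_samp <- suppressWarnings(as.integer(top[4]))
  if (any(is.na(c(n_sig, fs, n_samp)))) {
    abort(sprintf("Corrupt WFDB header fields in %s", hea))
  }
  sig <- lines[2:(1 + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    # filename format gain(baseline)/units adcres adczero initval cksum bsize desc
    gain_field <- f[3]
    gain <- as.numeric(sub("^([0-9.eE+-]+).*", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else 0
    list(file = f[1], fmt = f[2], gain = gain, baseline = baseline,
         desc = f[length(f)])
  }
  sigs <- lapply(sig, parse_sig)
  descs <- vapply(sigs, `[[`, "", "desc")
  hit <- which(tolower(descs) == tolower(lead))
  if (length(hit) != 1) {
    abort(sprintf("Lead '%s' not found in %s (available: %s)", lead, hea,
                  paste(descs, collapse = ", ")))
  }
  if (any(vapply(sigs, `[[`, "", "fmt") != "16")) {
    abort(sprintf("Only WFDB format 16 is supported (%s)", hea))
  }
  dat <- file.path(dirname(hea), sigs[[hit]]$file)
  if (!file.exists(dat)) abort(sprintf("WFDB signal file not found: %s", dat))
  raw <- readBin(dat, what = "integer", size = 2, signed = TRUE,
                 endian = "little", n = n_sig * n_samp)
  if (length(raw) < n_sig * n_samp) {
    abort(sprintf("WFDB signal file %s is truncated.", dat))
  }
  channel <- raw[seq(hit, by = n_sig, length.out = n_samp)]
  gain <- sigs[[hit]]$gain
  if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default adu/mV
  mv <- (channel - sigs[[hit]]$baseline) / gain
  id <- parse_record_identity(record_name, manifest)
  ecg_record(mv, fs, subject_id = id$subject_id, session_id = id$session_id,
             lead = descs[hit])
}

#' Write a record as a WFDB format-16 file pair
#'
#' Counterpart of [read_wfdb()]; mainly used to export synthetic data and in
#' round-trip tests.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory.
#' @param record_name File stem; defaults to `<subject>_<session>`.
#' @param gain ADC units per millivolt.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, record_name = NULL, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  record_name <- record_name %||% paste0(record$subject_id, "_", record$session_id)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(record$samples)
  hea <- file.path(dir, paste0(record_name, ".hea"))
  dat_name <- paste0(record_name, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", record_name, record$fs, n),
    sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat_name, gain, record$lead)
  ), hea)
  adu <- as.integer(round(pmax(pmin(record$samples * gain, 32767), -32768)))
  writeBin(adu, file.path(dir, dat_name), size = 2, endian = "little")
  invisible(hea)
}

#' Read an ECG trace from a one-column CSV file
#'
#' @param path Path to the file (one numeric amplitude per row).
#' @param fs Sampling rate in Hz.
#' @param header Does the file start with a header line to skip?
#' @param manifest Optional manifest tibble from [read_manifest()].
#' @inheritParams ecg_record
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs, header = FALSE, lead = "i", manifest = NULL) {
  if (!file.exists(path)) abort(sprintf("CSV not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("CSV %s is empty.", path))
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    abort(sprintf("CSV %s: non-numeric or non-finite value at data row %d ('%s').",
                  path, bad[1], trimws(lines[bad[1]])))
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  id <- parse_record_identity(stem, manifest)
  ecg_record(vals, fs, subject_id = id$subject_id, session_id = id$session_id,
             lead = lead)
}

#' Write an ECG record as a one-column CSV file
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  writeLines(format(record$samples, digits = 10, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Band-pass preprocess an ECG record
#'
#' Zero-phase band-pass conditioning before fiducial detection: the squared
#' magnitude response of a 4th-order Butterworth band-pass (the response a
#' forward-backward filter pair would have) is applied in the frequency
#' domain after symmetric padding. The filter is exactly zero-phase, so
#' fiducial positions do not shift; DC and drift below `low_hz` are
#' suppressed and content above `high_hz` is removed. `low_hz = 0` skips the
#' high-pass factor.
#'
#' @param record An [ecg_record()].
#' @param low_hz,high_hz Band edges in Hz; `0 <= low_hz < high_hz < fs/2`.
#' @param order Butterworth order of each band edge (default 4; the applied
#'   response is its forward-backward square).
#' @return A filtered [ecg_record()] of identical length and sampling rate.
#' @export
preprocess_ecg <- function(record, low_hz = 0.5, high_hz = 40, order = 4) {
  stopifnot(inherits(record, "ecg_record"))
  nyq <- record$fs / 2
  if (low_hz < 0 || low_hz >= high_hz) abort("Need 0 <= low_hz < high_hz.")
  if (high_hz >= nyq) {
    abort(sprintf("high_hz (%g) must be below the Nyquist frequency (%g).",
                  high_hz, nyq))
  }
  out <- record
  out$samples <- bandpass_zerophase(record$samples, record$fs, low_hz,
                                    high_hz, order)
  out$meta$preprocessed <- c(low_hz = low_hz, high_hz = high_hz)
  out
}

#' Resample a record to a new sampling rate
#'
#' Linear-interpolation resampling on the common time axis. Duration is
#' preserved to within one sample period and ground-truth fiducial indices are
#' rescaled (sample `i` at rate `fs` maps to time `(i-1)/fs`).
#'
#' @param record An [ecg_record()].
#' @param target_fs Target sampling rate in Hz.
#' @return An [ecg_record()] at `target_fs`.
#' @export
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "ecg_record"))
  stopifnot_scalar_number(target_fs, "target_fs")
  if (target_fs <= 0) abort("`target_fs` must be positive.")
  if (target_fs == record$fs) return(record)
  n <- length(record$samples)
  t_old <- (seq_len(n) - 1) / record$fs
  n_new <- round(n * target_fs / record$fs)
  t_new <- (seq_len(n_new) - 1) / target_fs
  y <- approx(t_old, record$samples, xout = pmin(t_new, max(t_old)),
              method = "linear", rule = 2)$y
  out <- record
  out$samples <- y
  out$fs <- target_fs
  if (!is.null(record$truth_fiducials)) {
    r <- target_fs / record$fs
    out$truth_fiducials <- lapply(record$truth_fiducials, function(idx) {
      pmin(pmax(as.integer(round((idx - 1) * r)) + 1L, 1L), n_new)
    })
  }
  out
}
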