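#' Continuous wavelet transform scalogram
#'
#' Computes the magnitude of the continuous wavelet transform of a segment
#' with an analytic Morlet mother wavelet (centre frequency `omega0 = 6`),
#' evaluated at logarithmically spaced scales covering `[f_min, f_max]` with
#' `voices_per_octave` scales per octave. The transform is computed in the
#' frequency domain (FFT) after symmetric padding to the next power of two of
#' at least twice the segment length, then cropped back, which keeps
#' cone-of-influence edge artefacts out of short windows. The wavelet is
#' normalized to unit peak in the frequency domain, so a pure sinusoid of
#' amplitude A yields a ridge of magnitude approximately A at its frequency,
#' and the transform is linear in the signal.
#'
#' Rows are ordered from the highest scale frequency (top) to the lowest
#' (bottom); columns correspond to the segment's time samples.
#'
#' @param samples Numeric vector (length >= 8).
#' @param fs Sampling rate in Hz.
#' @param f_min,f_max Frequency range in Hz; `f_max` defaults to
#'   `min(40, fs/2)` to match the preprocessing band and must not exceed
#'   `fs/2`.
#' @param voices_per_octave Scales per octave (>= 1, default 12).
#' @param omega0 Morlet centre frequency (rad).
#' @return A `scalogram` object: list with `magnitudes` (matrix, scales x
#'   time), `scale_frequencies` (Hz, one per row, decreasing) and `fs`.
#' @export
cwt_scalogram <- function(samples, fs, f_min = 0.5, f_max = NULL,
                          voices_per_octave = 12, omega0 = 6) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 8) abort("`samples` must have length >= 8.")
  f_max <- f_max %||% min(40, fs / 2)
  if (f_max > fs / 2) abort("`f_max` must not exceed fs/2.")
  if (f_min >= f_max) abort("Need f_min < f_max.")
  if (voices_per_octave < 1) abort("`voices_per_octave` must be >= 1.")
  n_oct <- log2(f_max / f_min)
  n_scales <- floor(n_oct * voices_per_octave) + 1L
  freqs <- f_max / 2^((seq_len(n_scales) - 1) / voices_per_octave)  # high -> low
  scales <- omega0 / (2 * pi * freqs) * fs                          # in samples
  L <- next_pow2(max(2L * n, 64L))
  xp <- pad_symmetric(samples, L)
  off <- (L - n) %/% 2L  # pad_symmetric centres the signal
  Fx <- fft(xp)
  omega <- 2 * pi * (seq_len(L) - 1) / L
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  mags <- matrix(0, n_scales, n)
  pos <- omega > 0
  for (j in seq_len(n_scales)) {
    psi <- numeric(L)
    psi[pos] <- exp(-0.5 * (scales[j] * omega[pos] - omega0)^2)
    w <- fft(Fx * psi, inverse = TRUE) / L
    mags[j, ] <- Mod(w[(off + 1L):(off + n)])
  }
  structure(
    list(magnitudes = mags, scale_frequencies = freqs, fs = fs),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales (%.2f-%.2f Hz) x %d samples @ %g Hz\n",
              nrow(x$magnitudes), min(x$scale_frequencies),
              max(x$scale_frequencies), ncol(x$magnitudes), x$fs))
  invisible(x)
}

#' 256-entry jet-like colormap
#'
#' @return A 256 x 3 matrix of RGB values in `[0, 1]`.
#' @export
jet_colormap <- function() {
  x <- seq(0, 1, length.out = 256)
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  cbind(
    r = clamp01(1.5 - abs(4 * x - 3)),
    g = clamp01(1.5 - abs(4 * x - 2)),
    b = clamp01(1.5 - abs(4 * x - 1))
  )
}

bilinear_resize <- function(m, h, w) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(EBImage::resize(m, w = h, h = w))  # EBImage: w = rows dim1
  }
  # fallback: separable linear interpolation
  nr <- nrow(m); nc <- ncol(m)
  ri <- if (h == 1) 1 else seq(1, nr, length.out = h)
  ci <- if (w == 1) 1 else seq(1, nc, length.out = w)
  r0 <- pmin(floor(ri), nr - 1); rf <- ri - r0
  tmp <- m[r0, , drop = FALSE] * (1 - rf) + m[r0 + 1, , drop = FALSE] * rf
  c0 <- pmin(floor(ci), nc - 1); cf <- ci - c0
  t(t(tmp[, c0, drop = FALSE]) * (1 - cf) + t(tmp[, c0 + 1, drop = FALSE]) * cf)
}

#' Render a scalogram as a fixed-size color image
#'
#' Magnitudes are min-max normalized to `[0, 1]` per image, mapped through a
#' 256-entry jet-like colormap, and bilinearly resized to `size x size`.
#' Low frequencies appear at the bottom of the image (row order of
#' [cwt_scalogram()] is already high-to-low frequency, i.e. top-to-bottom).
#' An all-constant scalogram maps to the lowest colormap entry rather than
#' erroring.
#'
#' @param scalogram A `scalogram` object (or a bare magnitude matrix).
#' @param size Output height and width in pixels (default 224).
#' @return A `size x size x 3` integer array with values in `[0, 255]`.
#' @export
scalogram_image <- function(scalogram, size = 224) {
  m <- if (inherits(scalogram, "scalogram")) scalogram$magnitudes else scalogram
  if (!length(m)) abort("Empty scalogram.")
  rng <- range(m)
  norm <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  resized <- bilinear_resize(norm, size, size)
  resized <- pmin(pmax(resized, 0), 1)
  cmap <- jet_colormap()
  idx <- pmin(255L, as.integer(floor(resized * 256))) + 1L
  arr <- array(0L, c(size, size, 3))
  for (ch in 1:3) {
    arr[, , ch] <- as.integer(round(matrix(cmap[idx, ch], size, size) * 255))
  }
  arr
}

#' Convert a segment table to scalogram images
#'
#' Runs [cwt_scalogram()] and [scalogram_image()] over every segment of a
#' segment tibble. Variable-length schemes (R-R, P-P) should be passed
#' through [resample_to_length()] first.
#'
#' @param segments A segment tibble.
#' @param fs Sampling rate of the segments in Hz.
#' @param size Image side length in pixels.
#' @param ... Passed to [cwt_scalogram()].
#' @return The tibble with an added list-column `image` (and `samples`
#'   retained).
#' @export
segments_to_images <- function(segments, fs, size = 224, ...) {
  segments$image <- purrr::map(segments$samples, function(x) {
    scalogram_image(cwt_scalogram(x, fs, ...), size = size)
  })
  segments
}

#' Write an image array as a PNG file
#'
#' @param image `H x W x 3` array with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("Package 'png' is required for PNG export.")
  }
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @export
autoplot.scalogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    scale_hz = object$scale_frequencies,
    time_s = (seq_len(ncol(object$magnitudes)) - 1) / object$fs
  )
  df$magnitude <- as.vector(t(object$magnitudes))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$scale_hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|CWT|")
}
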