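#' @importFrom rlang .data abort warn
#' @importFrom stats approx fft quantile sd rnorm runif qchisq pchisq
#' @importFrom utils head tail read.table write.table
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# centered moving average; width forced odd, edges use shrinking windows
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  k <- stats::filter(x, rep(1 / width, width), sides = 2)
  k <- as.numeric(k)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(half)) {
    k[i] <- mean(x[1:(i + half)])
    k[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  k
}

# magnitude of the analytic signal (FFT-based Hilbert envelope)
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# symmetric (mirror) padding to total length L, signal centred
pad_symmetric <- function(x, L) {
  n <- length(x)
  if (L <= n) return(x)
  extra <- L - n
  left <- extra %/% 2
  i <- (1L - left):(L - left)
  m <- 2L * n
  j <- ((i - 1L) %% m + m) %% m
  idx <- ifelse(j < n, j + 1L, m - j)
  x[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# odd (antisymmetric) signal extension to total length L, signal centred;
# continuous in value and slope at the joins, so edge leakage into a
# frequency-domain filter's passband stays small
pad_odd <- function(x, L) {
  n <- length(x)
  if (L <= n) return(x)
  extend_right <- function(v, m) {
    while (m > 0) {
      n0 <- length(v)
      k <- min(m, n0 - 1L)
      v <- c(v, 2 * v[n0] - v[seq(n0 - 1L, by = -1L, length.out = k)])
      m <- m - k
    }
    v
  }
  left <- (L - n) %/% 2L
  right <- L - n - left
  out <- rev(extend_right(rev(x), left))
  extend_right(out, right)
}

# Zero-phase band-pass: applies the squared magnitude response of an
# order-`order` Butterworth band-pass (the response of a forward-backward
# filter pair) in the frequency domain, after odd-extension padding that
# keeps circular edge effects out of the signal. Exactly zero-phase; DC is
# removed exactly when low_hz > 0.
bandpass_zerophase <- function(x, fs, low_hz, high_hz, order = 4) {
  n <- length(x)
  pad <- if (low_hz > 0) round(4 * fs / low_hz) else round(0.5 * fs)
  L <- next_pow2(n + 2 * min(pad, 8L * n))
  xp <- pad_odd(x, L)
  off <- (L - n) %/% 2L
  nu <- (seq_len(L) - 1) / L * fs
  # warped squared frequency: smooth and periodic across 0 and Nyquist, so
  # the response has no derivative kinks (which would ring in time)
  f2 <- (fs / pi * sinpi(nu / fs))^2
  G <- rep(1, L)
  if (low_hz > 0) {
    G <- ifelse(f2 > 0, 1 / (1 + (low_hz^2 / pmax(f2, 1e-300))^order), 0)
  }
  G <- G / (1 + (f2 / high_hz^2)^order)
  y <- Re(fft(fft(xp) * G, inverse = TRUE) / L)
  y[(off + 1L):(off + n)]
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
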