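#' Morlet frequency grid
#'
#' Geometric (log-spaced) frequency grid used for all scaleograms:
#' `voices` frequencies per octave from `f_lo` to `f_hi`. The default
#' (48 voices/octave over 0.3-5.0 Hz, ~197 frequencies) keeps the spacing
#' under 0.05 Hz throughout the 0.6-3 Hz band where walking cadence lives.
#'
#' @param f_lo,f_hi grid bounds in Hz.
#' @param voices frequencies per octave.
#' @return Increasing numeric vector of frequencies in Hz.
#' @export
cwt_freq_grid <- function(f_lo = 0.3, f_hi = 5.0, voices = 48) {
  n_oct <- log2(f_hi / f_lo)
  k <- 0:ceiling(n_oct * voices)
  f <- f_lo * 2^(k / voices)
  f[f <= f_hi + 1e-12]
}

# Morlet (omega0 = 6) transfer matrix in the FFT domain for a segment of
# length n at rate fs: one column per analysis frequency. L2 normalization
# (sqrt(2*pi*s/dt)) keeps white noise flat across scales; a pure tone's
# response then grows like sqrt(scale), i.e. ~1/sqrt(f).
morlet_transfer <- function(n, fs, freqs, omega0 = 6) {
  dt <- 1 / fs
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- (1 / freqs) / fourier_factor          # seconds
  k <- 0:(n - 1L)
  omega <- 2 * pi * ifelse(k <= n / 2, k, k - n) / (n * dt)  # rad/s
  H <- matrix(0, nrow = n, ncol = length(freqs))
  pos <- omega > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    H[pos, j] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-0.5 * (s * omega[pos] - omega0)^2)
  }
  H
}

# small cache: transfer matrices are reused across windows of equal length
.cwt_cache <- new.env(parent = emptyenv())

cached_transfer <- function(n, fs, freqs, omega0) {
  key <- paste(n, fs, omega0, length(freqs),
               format(freqs[1L], digits = 12),
               format(freqs[length(freqs)], digits = 12), sep = "|")
  H <- .cwt_cache[[key]]
  if (is.null(H)) {
    H <- morlet_transfer(n, fs, freqs, omega0)
    assign(key, H, envir = .cwt_cache)
  }
  H
}

# |CWT| of a real segment: rows = time samples, cols = frequencies
cwt_magnitude <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(max(n, 2L)))
  xp <- c(x, numeric(npad - n))
  H <- cached_transfer(npad, fs, freqs, omega0)
  X <- fft(xp)
  W <- stats::mvfft(X * H, inverse = TRUE) / npad
  abs(W[seq_len(n), , drop = FALSE])
}

#' Continuous wavelet scaleogram of a 1-second window
#'
#' Transforms one detector window into the time-frequency plane with a
#' Morlet wavelet (center frequency omega0 = 6). Up to 2 s of neighboring
#' samples on each side are included in the transform to push wavelet edge
#' effects outside the window; the window mean is removed beforehand and
#' the context columns are trimmed afterwards, so only the window's own
#' 1 second of coefficients is returned.
#'
#' @param window numeric vector of magnitude samples covering 1 s at `fs`.
#' @param before,after neighboring magnitude samples (up to 2 s each) for
#'   edge-effect mitigation; may be empty.
#' @param fs sampling rate in Hz (the 10 Hz working rate).
#' @param freqs analysis frequency grid, see [cwt_freq_grid()].
#' @param omega0 Morlet center frequency parameter.
#' @return An object of class `scaleogram`: list with `freqs` (Hz,
#'   increasing), `times` (s, within-window sample offsets) and `magnitude`
#'   (|C(f, tau)| matrix, frequencies x time).
#' @export
cwt_decompose <- function(window, before = numeric(0), after = numeric(0),
                          fs = 10, freqs = cwt_freq_grid(), omega0 = 6) {
  window <- as.numeric(window)
  ctx_max <- as.integer(round(2 * fs))
  before <- tail(as.numeric(before), ctx_max)
  after <- head(as.numeric(after), ctx_max)
  seg <- c(before, window, after) - mean(window)
  M <- cwt_magnitude(seg, fs, freqs, omega0)
  idx <- length(before) + seq_along(window)
  structure(list(freqs = freqs,
                 times = (seq_along(window) - 1L) / fs,
                 magnitude = t(M[idx, , drop = FALSE])),
            class = "scaleogram")
}

#' @export
print.scaleogram <- function(x, ...) {
  cat(sprintf("Scaleogram: %d frequencies (%.3g-%.3g Hz) x %d time steps\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times)))
  invisible(x)
}

# Local maxima of a profile matrix (rows = windows, cols = frequencies):
# interior bins that dominate both neighbors (ties allowed), end bins only
# when strictly above their single neighbor. Monotone shoulders leaking
# across a band edge therefore never count as a region's peak.
profile_local_max <- function(P) {
  n <- ncol(P)
  L <- matrix(FALSE, nrow = nrow(P), ncol = n)
  if (n >= 3L) {
    mid <- 2:(n - 1L)
    L[, mid] <- P[, mid, drop = FALSE] >= P[, mid - 1L, drop = FALSE] &
      P[, mid, drop = FALSE] >= P[, mid + 1L, drop = FALSE]
  }
  if (n >= 2L) {
    L[, 1L] <- P[, 1L] > P[, 2L]
    L[, n] <- P[, n] > P[, n - 1L]
  } else if (n == 1L) L[, 1L] <- TRUE
  L
}
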