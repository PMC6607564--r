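# Zero-phase FIR filtering and small spectral helpers shared across the
# preprocessing and F0-encoding paths.

#' Design a linear-phase FIR filter (Hamming window)
#'
#' Thin wrapper around [signal::fir1()] choosing the order from the lowest
#' cutoff: five periods of the cutoff frequency, long enough that the squared
#' (zero-phase) response stays within 1% across the passband.
#'
#' @param fs_hz sampling rate (Hz)
#' @param low_hz low-pass cutoff (Hz) or `NULL`
#' @param high_hz high-pass cutoff (Hz) or `NULL`; both given = band-pass
#' @param order optional filter order override (even integer)
#' @return numeric vector of filter coefficients
#' @export
design_fir <- function(fs_hz, low_hz = NULL, high_hz = NULL, order = NULL) {
  if (is.null(low_hz) && is.null(high_hz)) stop("need at least one cutoff")
  cuts <- c(high_hz, low_hz)
  if (any(cuts <= 0) || any(cuts >= fs_hz / 2)) {
    stop("cutoffs must lie in (0, fs/2)")
  }
  if (is.null(order)) {
    order <- 2L * ceiling(2.5 * fs_hz / min(cuts))
  }
  type <- if (!is.null(low_hz) && !is.null(high_hz)) {
    "pass"
  } else if (!is.null(low_hz)) "low" else "high"
  w <- cuts / (fs_hz / 2)
  as.numeric(signal::fir1(order, w, type = type))
}

#' Zero-phase FIR filtering
#'
#' Filters forward and backward (equivalently: convolves with the filter's
#' autocorrelation), so the magnitude response is squared and the phase
#' response is exactly zero -- an impulse at sample t stays at sample t.
#' Accepts a vector or a matrix (rows are filtered independently), which keeps
#' bootstrap-replicate filtering vectorised. Signals are zero-padded at the
#' edges; the first/last half filter length is therefore attenuated towards
#' zero, which is benign for baseline-corrected epochs whose edges carry no
#' measured feature.
#'
#' @param x numeric vector, or matrix with one signal per row
#' @param fs_hz sampling rate (Hz)
#' @param low_hz,high_hz cutoffs as in [design_fir()]
#' @param order optional FIR order override
#' @return filtered object of the same shape as `x`
#' @export
filter_waveform <- function(x, fs_hz, low_hz = NULL, high_hz = NULL,
                            order = NULL) {
  h <- design_fir(fs_hz, low_hz = low_hz, high_hz = high_hz, order = order)
  g <- stats::convolve(h, h, type = "open")   # symmetric, zero-phase kernel
  half <- (length(g) - 1L) / 2L
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nfft <- stats::nextn(n + length(g), 2)
  G <- stats::fft(c(g, numeric(nfft - length(g))))
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nfft - n))))
  y <- Re(stats::mvfft(X * G, inverse = TRUE)) / nfft
  out <- t(y)[, half + seq_len(n), drop = FALSE]
  if (vec) drop(out) else out
}

#' Discrete Hilbert transform
#'
#' Imaginary part of the analytic signal, computed in the frequency domain.
#' `hilbert_transform(cos)` is `sin` (a 90 degree phase lag of every
#' positive-frequency component).
#'
#' @param x numeric vector
#' @return numeric vector, the Hilbert transform of `x`
#' @export
hilbert_transform <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(X * h, inverse = TRUE) / n)
}

#' Band-limited resampling by FFT
#'
#' Exact sinc (band-limited) resampling of a finite signal to a new number of
#' samples spanning the same duration, by truncating or zero-padding the
#' discrete spectrum. Truncation is ideal anti-alias low-pass filtering at
#' the new Nyquist frequency.
#'
#' @param x numeric vector
#' @param n_out target number of samples
#' @return numeric vector of length `n_out`
#' @export
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  keep <- min(n_in, n_out)
  half <- keep %/% 2
  idx_lo <- seq_len(half + 1)
  Y[idx_lo] <- X[idx_lo]
  if (half > 0) {
    Y[n_out - seq_len(half) + 1] <- X[n_in - seq_len(half) + 1]
  }
  if (keep %% 2 == 0 && n_out != n_in) {
    # split the Nyquist bin symmetrically to keep the signal real
    nyq <- X[half + 1]
    if (n_out > n_in) {
      Y[half + 1] <- nyq / 2
      Y[n_out - half + 1] <- Conj(nyq) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}
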