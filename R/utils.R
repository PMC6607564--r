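#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic components of the package draw their randomness through
#' seeds derived deterministically from one master seed, so that a whole
#' simulated study is reproducible from a single integer.
#'
#' @param seed master seed (integer).
#' @param ... further integer or character keys (e.g. subject index,
#'   condition label) mixed into the derived seed.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time axis of a sampled waveform
#' @param n number of samples
#' @param fs_hz sampling rate (Hz)
#' @param t0_ms time of the first sample (ms)
#' @return numeric vector of times in ms
#' @keywords internal
time_axis <- function(n, fs_hz, t0_ms = 0) t0_ms + (seq_len(n) - 1) / fs_hz * 1000

#' Frequency of the periodogram peak of a signal
#'
#' Zero-padded FFT magnitude peak; used to verify the spectral content of
#' extracted fundamental waveforms and intrinsic mode functions.
#'
#' @param x numeric signal
#' @param fs_hz sampling rate in Hz
#' @param nfft FFT length (zero-padded); default gives sub-Hz resolution
#'   for short tokens.
#' @param fmin,fmax optional band restriction (Hz) for the peak search.
#' @return peak frequency in Hz
#' @export
spectral_peak <- function(x, fs_hz, nfft = max(2^15, length(x)),
                          fmin = 0, fmax = fs_hz / 2) {
  x <- x - mean(x)
  X <- abs(stats::fft(c(x, numeric(nfft - length(x)))))[seq_len(nfft %/% 2)]
  f <- (seq_len(nfft %/% 2) - 1) * fs_hz / nfft
  keep <- f >= fmin & f <= fmax
  f[keep][which.max(X[keep])]
}

#' Power of a signal within a frequency band (periodogram sum)
#' @keywords internal
band_power <- function(x, fs_hz, fmin, fmax, nfft = max(2^14, length(x))) {
  x <- x - mean(x)
  X <- abs(stats::fft(c(x, numeric(nfft - length(x)))))[seq_len(nfft %/% 2)]^2
  f <- (seq_len(nfft %/% 2) - 1) * fs_hz / nfft
  sum(X[f >= fmin & f <= fmax])
}
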