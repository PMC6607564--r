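# F0-encoding analysis: extraction of the stimulus fundamental waveform via
# empirical mode decomposition, complex cross-correlation of averaged
# responses with that waveform and its Hilbert transform, and a one-sample
# Hotelling T-squared presence test on segmented responses.

#' Extract the fundamental (F0) waveform of the stimulus
#'
#' The stimulus (at the response sampling rate) has its onset-burst portion
#' zeroed so the fundamental comes exclusively from the voiced vowel;
#' `n_concat` copies are concatenated to give the decomposition enough
#' cycles, EMD is run, and the fundamental is the IMF whose spectral peak
#' falls inside `f0_band_hz` (the one with most in-band power if several
#' qualify). The selected IMF is cut back into the `n_concat` segments,
#' which are averaged into a single token-length F0 waveform whose frequency
#' content is then verified (spectral peak + mean interwave interval).
#'
#' @param stim a `stimulus` (resample with [resample_stimulus()] first;
#'   20 kHz is the convention)
#' @param n_concat number of concatenated repetitions (default 10)
#' @param zero_onset_ms onset portion zeroed before decomposition (default
#'   10 ms, the burst duration)
#' @param f0_band_hz band within which the fundamental IMF's spectral peak
#'   must fall (default 80-150 Hz)
#' @return object of class `f0_waveform`: `samples`, `fs_hz`,
#'   `verified_peak_hz`, `mean_interwave_interval_ms`, `imf_index`
#' @export
extract_fundamental <- function(stim, n_concat = 10, zero_onset_ms = 10,
                                f0_band_hz = c(80, 150)) {
  stopifnot(inherits(stim, "stimulus"))
  fs <- stim$fs_hz
  x <- stim$samples
  x[time_axis(length(x), fs) < zero_onset_ms] <- 0
  xc <- rep(x, n_concat)
  dec <- emd(xc)
  if (nrow(dec$imfs) == 0) stop("no IMFs could be extracted from the stimulus")
  peaks <- apply(dec$imfs, 1, spectral_peak, fs_hz = fs)
  in_band <- which(peaks >= f0_band_hz[1] & peaks <= f0_band_hz[2])
  if (length(in_band) == 0) {
    stop("no IMF has its spectral peak inside the F0 band [",
         f0_band_hz[1], ", ", f0_band_hz[2], "] Hz")
  }
  pw <- vapply(in_band, function(i) {
    band_power(dec$imfs[i, ], fs, f0_band_hz[1], f0_band_hz[2])
  }, numeric(1))
  sel <- in_band[which.max(pw)]
  seg <- matrix(dec$imfs[sel, ], ncol = n_concat)
  f0_samples <- rowMeans(seg)
  # sifting spreads some energy across the zeroed onset; re-zero it so the
  # fundamental waveform comes exclusively from the vowel
  f0_samples[time_axis(length(f0_samples), fs) < zero_onset_ms] <- 0

  pk_hz <- spectral_peak(f0_samples, fs)
  ex <- find_extrema(f0_samples)
  iwi <- if (length(ex$maxima) >= 2) {
    mean(diff(ex$maxima)) / fs * 1000
  } else {
    NA_real_
  }
  structure(
    list(samples = f0_samples, fs_hz = fs, verified_peak_hz = pk_hz,
         mean_interwave_interval_ms = iwi, imf_index = sel),
    class = "f0_waveform"
  )
}

#' @export
print.f0_waveform <- function(x, ...) {
  cat(sprintf(
    "<f0_waveform> %d samples @ %g Hz; spectral peak %.1f Hz; mean interwave interval %.2f ms\n",
    length(x$samples), x$fs_hz, x$verified_peak_hz,
    x$mean_interwave_interval_ms))
  invisible(x)
}

#' Complex cross-correlation of a response with the F0 waveform
#'
#' The averaged response is low-pass filtered (default 300 Hz, below which
#' the token's F0 lies), its first `zero_first_ms` are set to zero and
#' anything after `end_ms` is disregarded, restricting the analysis to the
#' transition-period envelope-following response. The real part is the
#' cross-correlation of the trimmed response with the F0 waveform and the
#' imaginary part the cross-correlation with its Hilbert transform
#' (sum-of-products at each lag divided by the F0 waveform length). The
#' envelope is the modulus; its maximum over `lag_window_ms` gives the F0
#' encoding latency and amplitude.
#'
#' @param resp an `averaged_response` on the corrected time axis
#' @param f0 an `f0_waveform` at the same sampling rate
#' @param zero_first_ms response samples before this time are zeroed
#' @param end_ms response samples after this time are dropped
#' @param lowpass_hz zero-phase low-pass cutoff applied to the response
#'   (`NULL` to skip)
#' @param lag_window_ms lag range searched for the envelope maximum
#' @return object of class `f0_xcorr`: `lags_ms`, `real`, `imag`,
#'   `envelope`, `latency_ms`, `amplitude`
#' @export
complex_xcorr <- function(resp, f0, zero_first_ms = 20, end_ms = 50,
                          lowpass_hz = 300, lag_window_ms = c(0, 20)) {
  stopifnot(inherits(resp, "averaged_response"), inherits(f0, "f0_waveform"))
  if (resp$fs_hz != f0$fs_hz) stop("response and F0 waveform sampling rates differ")
  fs <- resp$fs_hz
  w <- resp$waveform
  if (!is.null(lowpass_hz)) w <- filter_waveform(w, fs, low_hz = lowpass_hz)
  t <- times_ms(resp)
  keep <- t >= 0 & t <= end_ms
  r <- w[keep]
  r[t[keep] < zero_first_ms] <- 0
  if (length(r) == 0) stop("no response samples left after trimming")

  if (lag_window_ms[1] > lag_window_ms[2]) stop("empty lag window")
  lags <- seq(round(lag_window_ms[1] * fs / 1000),
              round(lag_window_ms[2] * fs / 1000))
  g <- f0$samples
  gh <- hilbert_transform(g)
  nf <- length(g)
  rpad <- c(r, numeric(max(0, max(lags) + nf - length(r))))
  xr <- vapply(lags, function(k) sum(g * rpad[k + seq_len(nf)]) / nf, numeric(1))
  xi <- vapply(lags, function(k) sum(gh * rpad[k + seq_len(nf)]) / nf, numeric(1))
  env <- sqrt(xr^2 + xi^2)
  j <- which.max(env)
  structure(
    list(lags_ms = lags / fs * 1000, real = xr, imag = xi, envelope = env,
         latency_ms = lags[j] / fs * 1000, amplitude = env[j]),
    class = "f0_xcorr"
  )
}

#' @export
print.f0_xcorr <- function(x, ...) {
  cat(sprintf("<f0_xcorr> envelope peak %.4g at %.2f ms (lags %.1f-%.1f ms)\n",
              x$amplitude, x$latency_ms, min(x$lags_ms), max(x$lags_ms)))
  invisible(x)
}

# split retained epochs into n_segments contiguous chunks per polarity and
# return one de-meaned alternating-polarity segment average per chunk
segment_averages <- function(epochs, n_segments) {
  pos <- which(epochs$polarity == 1)
  neg <- which(epochs$polarity == -1)
  per <- min(length(pos), length(neg)) %/% n_segments
  if (per < 1) stop("too few epochs per polarity to form ", n_segments,
                    " segments")
  vapply(seq_len(n_segments), function(s) {
    i <- (s - 1) * per + seq_len(per)
    de_mean((colMeans(epochs$data[pos[i], , drop = FALSE]) +
               colMeans(epochs$data[neg[i], , drop = FALSE])) / 2)
  }, numeric(ncol(epochs$data)))
}

#' One-sample Hotelling T-squared presence test for F0 encoding
#'
#' The epochs are divided into `n_segments` contiguous segments with an
#' equal polarity split (remainder epochs dropped). Each segment is averaged
#' (alternating polarity, de-meaned), complex cross-correlated with the F0
#' waveform, and the (real, imaginary) pair is read off at the lag obtained
#' from the full response. The segment pairs are tested against (0, 0) with
#' a one-sample Hotelling T-squared test:
#' `T2 = n * xbar' S^-1 xbar`, `F = (n - p) / (p (n - 1)) * T2` on
#' `(p = 2, n - 2)` degrees of freedom. The response is declared present
#' when `p < .05`.
#'
#' @param epochs an [epoch_set()] (post artifact rejection)
#' @param f0 an `f0_waveform`
#' @param latency_from_full lag (ms) of the envelope maximum of the
#'   full-response cross-correlation
#' @param n_segments number of segments (default 10)
#' @param corrections_ms time correction applied to the segment averages'
#'   axis, matching the full response
#' @param ... trimming/filter arguments passed to [complex_xcorr()]
#' @return list: `t2`, `df`, `p_value`, `present`, `segment_values`
#'   (n_segments x 2 matrix of real/imaginary parts), `n_segments`
#' @export
hotelling_t2 <- function(epochs, f0, latency_from_full, n_segments = 10,
                         corrections_ms = 0, ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  segs <- segment_averages(epochs, n_segments)
  vals <- t(apply(segs, 2, function(w) {
    resp <- structure(
      list(waveform = w, subaverages = matrix(w, nrow = 1),
           fs_hz = epochs$fs_hz, t0_ms = epochs$t0_ms - corrections_ms,
           n_epochs_used = NA_integer_, corrections_applied_ms = corrections_ms,
           filters_applied = character(0),
           condition = epochs$condition, subject = epochs$subject),
      class = "averaged_response"
    )
    xc <- complex_xcorr(resp, f0,
                        lag_window_ms = rep(latency_from_full, 2), ...)
    c(xc$real[1], xc$imag[1])
  }))
  n <- n_segments
  p <- 2
  xbar <- colMeans(vals)
  S <- stats::cov(vals)
  if (max(abs(vals)) == 0) {
    # no signal and no noise at all: trivially absent
    return(list(t2 = 0, df = c(p, n - p), p_value = 1, present = FALSE,
                segment_values = vals, n_segments = n))
  }
  if (!is.finite(rcond_2x2(S)) || rcond_2x2(S) < .Machine$double.eps * 100) {
    stop("degenerate segment covariance (identical segments?)")
  }
  t2 <- n * drop(t(xbar) %*% solve(S, xbar))
  f_stat <- (n - p) / (p * (n - 1)) * t2
  p_value <- stats::pf(f_stat, p, n - p, lower.tail = FALSE)
  list(t2 = t2, df = c(p, n - p), p_value = p_value,
       present = p_value < 0.05, segment_values = vals, n_segments = n)
}

rcond_2x2 <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Full F0-encoding analysis of one condition's epochs
#'
#' Composes the three steps: the full-response complex cross-correlation
#' (giving F0 encoding latency and amplitude), then the segmented Hotelling
#' T-squared presence test at that latency.
#'
#' @param epochs an [epoch_set()] (post artifact rejection)
#' @param f0 an `f0_waveform`
#' @param corrections_ms total time correction for this condition (ms)
#' @param n_segments segments for the presence test
#' @param lag_window_ms lag range searched for the envelope maximum
#' @param ... trimming/filter arguments (`zero_first_ms`, `end_ms`,
#'   `lowpass_hz`) applied identically to the full response and the segments
#' @return object of class `f0_encoding_result`: `latency_ms`, `amplitude`,
#'   `t2_statistic`, `p_value`, `present`, plus the underlying `xcorr`
#' @export
f0_encode <- function(epochs, f0, corrections_ms = 0, n_segments = 10,
                      lag_window_ms = c(0, 20), ...) {
  avg <- alternating_average(epochs)
  avg$t0_ms <- avg$t0_ms - corrections_ms
  avg$corrections_applied_ms <- corrections_ms
  xc <- complex_xcorr(avg, f0, lag_window_ms = lag_window_ms, ...)
  ht <- hotelling_t2(epochs, f0, latency_from_full = xc$latency_ms,
                     n_segments = n_segments, corrections_ms = corrections_ms,
                     ...)
  structure(
    list(latency_ms = xc$latency_ms, amplitude = xc$amplitude,
         t2_statistic = ht$t2, p_value = ht$p_value, present = ht$present,
         xcorr = xc, hotelling = ht),
    class = "f0_encoding_result"
  )
}

#' @export
print.f0_encoding_result <- function(x, ...) {
  cat(sprintf(
    "<f0_encoding_result> latency %.2f ms, amplitude %.4g, T2 = %.2f, p = %.3g (%s)\n",
    x$latency_ms, x$amplitude, x$t2_statistic, x$p_value,
    if (x$present) "present" else "absent"))
  invisible(x)
}
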