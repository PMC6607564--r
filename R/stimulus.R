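# Synthesis of the 40 ms five-formant [da]-like token used to evoke
# speech-ABRs: a 10 ms aperiodic onset burst followed by a voiced formant
# transition with a rising fundamental (103-125 Hz), realised as a glottal
# impulse train driving a cascade of five second-order formant resonators.

#' Specification of the synthetic [da] stimulus
#'
#' @param duration_ms total duration (default 40 ms)
#' @param onset_burst_ms duration of the aperiodic onset burst (default 10 ms)
#' @param f0_start_hz,f0_end_hz fundamental frequency at voicing onset and at
#'   stimulus end; interpolated linearly in between (defaults 103 and 125 Hz)
#' @param formant_start_hz,formant_end_hz centre frequencies of the five
#'   formants at voicing onset / stimulus end (Hz). Defaults: F1 220-720,
#'   F2 1700-1240, F3 2580-2500, F4 3600-3600, F5 4500-4500.
#' @param formant_bandwidths_hz resonator bandwidths (Hz); synthesis
#'   conventions, configurable.
#' @param voicing_ramp_ms linear rise time of voicing amplitude after the
#'   burst (gradual voicing onset, as in natural tokens)
#' @param glottal_bw_hz bandwidth of the glottal low-pass resonator shaping
#'   the impulse-train source (a Klatt-style voicing source: impulse train,
#'   second-order low-pass, first-difference radiation characteristic);
#'   smaller values tilt the source spectrum further towards the fundamental
#' @param synth_fs_hz synthesis sampling rate (default 48000 Hz)
#' @param burst_seed seed for the stochastic burst realisation
#' @return an object of class `stimulus_spec`
#' @export
stimulus_spec <- function(duration_ms = 40, onset_burst_ms = 10,
                          f0_start_hz = 103, f0_end_hz = 125,
                          formant_start_hz = c(220, 1700, 2580, 3600, 4500),
                          formant_end_hz = c(720, 1240, 2500, 3600, 4500),
                          formant_bandwidths_hz = c(90, 110, 170, 250, 300),
                          voicing_ramp_ms = 10, glottal_bw_hz = 80,
                          synth_fs_hz = 48000, burst_seed = 1L) {
  stopifnot(
    duration_ms > onset_burst_ms, onset_burst_ms >= 0,
    f0_start_hz <= f0_end_hz,
    length(formant_start_hz) == 5, length(formant_end_hz) == 5,
    length(formant_bandwidths_hz) == 5
  )
  if (any(formant_bandwidths_hz <= 0)) stop("formant bandwidths must be positive")
  if (any(c(formant_start_hz, formant_end_hz, f0_end_hz) >= synth_fs_hz / 2)) {
    stop("all frequencies must lie below the Nyquist frequency")
  }
  structure(
    list(duration_ms = duration_ms, onset_burst_ms = onset_burst_ms,
         f0_start_hz = f0_start_hz, f0_end_hz = f0_end_hz,
         formant_start_hz = formant_start_hz, formant_end_hz = formant_end_hz,
         formant_bandwidths_hz = formant_bandwidths_hz,
         voicing_ramp_ms = voicing_ramp_ms, glottal_bw_hz = glottal_bw_hz,
         synth_fs_hz = synth_fs_hz, burst_seed = as.integer(burst_seed)),
    class = "stimulus_spec"
  )
}

#' Instantaneous F0 track of a stimulus spec
#'
#' Linear interpolation from `f0_start_hz` at voicing onset (end of the
#' burst) to `f0_end_hz` at the end of the token. Times before voicing onset
#' return `NA` (unvoiced).
#'
#' @param spec a [stimulus_spec()]
#' @param t_ms times (ms, stimulus clock)
#' @return instantaneous F0 in Hz
#' @export
f0_track <- function(spec, t_ms) {
  frac <- (t_ms - spec$onset_burst_ms) / (spec$duration_ms - spec$onset_burst_ms)
  out <- spec$f0_start_hz + frac * (spec$f0_end_hz - spec$f0_start_hz)
  out[t_ms < spec$onset_burst_ms | t_ms > spec$duration_ms] <- NA_real_
  out
}

#' Voicing phase (cycles) along the stimulus
#'
#' Integral of the instantaneous F0 track from voicing onset, in cycles.
#' Glottal pulses fall where the phase crosses integer values.
#'
#' @param spec a [stimulus_spec()]
#' @param t_ms times (ms) at or after voicing onset
#' @return phase in cycles (0 at voicing onset)
#' @export
f0_phase <- function(spec, t_ms) {
  u <- (t_ms - spec$onset_burst_ms) / 1000
  len <- (spec$duration_ms - spec$onset_burst_ms) / 1000
  slope <- (spec$f0_end_hz - spec$f0_start_hz) / len
  spec$f0_start_hz * u + slope * u^2 / 2
}

# Time-varying second-order resonator (Klatt form): coefficients are
# recomputed per sample from linearly interpolated centre frequencies.
klatt_resonator <- function(x, f_hz, b_hz, fs) {
  T <- 1 / fs
  C <- -exp(-2 * pi * b_hz * T)
  B <- 2 * exp(-pi * b_hz * T) * cos(2 * pi * f_hz * T)
  A <- 1 - B - C
  y <- numeric(length(x))
  y1 <- 0; y2 <- 0
  for (n in seq_along(x)) {
    y[n] <- A[n] * x[n] + B[n] * y1 + C[n] * y2
    y2 <- y1
    y1 <- y[n]
  }
  y
}

#' Synthesize the [da]-like stimulus
#'
#' The first `onset_burst_ms` hold a seeded white-noise burst band-passed to
#' 1.5-5 kHz with 1 ms raised-cosine ramps (an aperiodic plosive release);
#' the remainder is voiced: an impulse train at the instantaneous F0, shaped
#' by a glottal low-pass resonator and a first-difference radiation
#' characteristic (the classic terminal-analog voicing source), driven
#' through a cascade of five time-varying second-order resonators whose
#' centre frequencies follow the linearly interpolated formant tracks. The
#' output is peak-normalised to 1.
#'
#' @param spec a [stimulus_spec()]
#' @return an object of class `stimulus`: list with `samples`, `fs_hz`,
#'   `polarity` (+1) and `spec`
#' @export
synthesize_da <- function(spec = stimulus_spec()) {
  fs <- spec$synth_fs_hz
  n <- round(spec$duration_ms * fs / 1000)
  t_ms <- time_axis(n, fs)
  voiced <- t_ms >= spec$onset_burst_ms

  # glottal source: unit impulse at every integer phase crossing, shaped by
  # a low-pass glottal resonator and differentiated (radiation)
  source <- numeric(n)
  ph <- floor(f0_phase(spec, t_ms[voiced]))
  pulse <- c(TRUE, diff(ph) >= 1)
  source[voiced][pulse] <- 1
  source <- klatt_resonator(source, rep(0, n), rep(spec$glottal_bw_hz, n), fs)
  source <- c(0, diff(source))

  # formant cascade with per-sample interpolated centre frequencies
  frac <- pmax(0, (t_ms - spec$onset_burst_ms) /
                    (spec$duration_ms - spec$onset_burst_ms))
  out <- source
  for (k in 1:5) {
    fk <- spec$formant_start_hz[k] +
      frac * (spec$formant_end_hz[k] - spec$formant_start_hz[k])
    out <- klatt_resonator(out, fk, rep(spec$formant_bandwidths_hz[k], n), fs)
  }
  if (spec$voicing_ramp_ms > 0) {
    out <- out * pmin(1, pmax(0, (t_ms - spec$onset_burst_ms) /
                                   spec$voicing_ramp_ms))
  }
  out[!voiced] <- 0

  # aperiodic onset burst: band-passed noise with raised-cosine ramps
  if (spec$onset_burst_ms > 0) {
    nb <- sum(!voiced)
    burst <- withr_seed(spec$burst_seed, stats::rnorm(nb))
    burst <- filter_waveform(burst, fs, low_hz = min(5000, fs / 2 - 1),
                             high_hz = 1500)
    nr <- round(0.001 * fs)
    ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    burst[seq_len(nr)] <- burst[seq_len(nr)] * ramp
    burst[nb - nr + seq_len(nr)] <- burst[nb - nr + seq_len(nr)] * rev(ramp)
    burst <- burst / max(abs(burst)) * 0.5 * max(abs(out))
    out[!voiced] <- burst
  }

  out <- out / max(abs(out))
  structure(list(samples = out, fs_hz = fs, polarity = 1L, spec = spec),
            class = "stimulus")
}

# evaluate expr under a temporary seed without disturbing the global RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Invert stimulus polarity
#'
#' Negates the samples and flips the polarity flag; used to evoke responses
#' with two opposite stimulus polarities whose averages cancel
#' polarity-locked contamination (stimulus artifact, cochlear microphonic).
#'
#' @param stim a `stimulus`
#' @return the polarity-reversed `stimulus`
#' @export
invert_polarity <- function(stim) {
  stopifnot(inherits(stim, "stimulus"))
  stim$samples <- -stim$samples
  stim$polarity <- -stim$polarity
  stim
}

#' Resample a stimulus
#'
#' Band-limited (FFT) resampling preserving duration to within one sample
#' period; spectrum truncation at the new Nyquist acts as the anti-alias
#' low-pass. Typically used to bring the 48 kHz token to the 20 kHz response
#' sampling rate.
#'
#' @param stim a `stimulus`
#' @param target_fs_hz new sampling rate (Hz)
#' @return resampled `stimulus`
#' @export
resample_stimulus <- function(stim, target_fs_hz) {
  stopifnot(inherits(stim, "stimulus"))
  if (target_fs_hz <= 0) stop("target_fs_hz must be positive")
  if (target_fs_hz == stim$fs_hz) return(stim)
  n_out <- round(length(stim$samples) * target_fs_hz / stim$fs_hz)
  stim$samples <- fft_resample(stim$samples, n_out)
  stim$fs_hz <- target_fs_hz
  stim
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> %d samples @ %g Hz (%.1f ms), polarity %+d\n",
              length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz * 1000, x$polarity))
  invisible(x)
}

#' Write a stimulus as a mono WAV file plus a JSON sidecar
#'
#' Minimal RIFF writer (16-bit PCM). The stimulus spec and polarity are
#' stored in `<path>.json`.
#'
#' @param stim a `stimulus`
#' @param path output `.wav` path
#' @return `path`, invisibly
#' @export
write_stimulus_wav <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus"))
  pcm <- as.integer(round(pmax(-1, pmin(1, stim$samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(stim$fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(stim$fs_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  meta <- c(stim$spec, list(polarity = stim$polarity))
  class(meta) <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a stimulus written by [write_stimulus_wav()]
#'
#' @param path `.wav` path (with `<path>.json` sidecar alongside)
#' @return a `stimulus`
#' @export
read_stimulus_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4); readBin(con, "integer", size = 4, endian = "little")
  readChar(con, 8)
  readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")
  fs <- readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")
  readChar(con, 4)
  nbytes <- readBin(con, "integer", size = 4, endian = "little")
  pcm <- readBin(con, "integer", n = nbytes / 2, size = 2, endian = "little")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(stimulus_spec, meta[setdiff(names(meta), "polarity")])
  structure(list(samples = pcm / 32767, fs_hz = fs,
                 polarity = as.integer(meta$polarity), spec = spec),
            class = "stimulus")
}
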