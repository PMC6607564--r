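# Epoch-level simulation of speech-ABR recordings: deterministic clean
# response + polarity-locked contamination + EEG noise + occasional
# large-amplitude artifacts, under the standard acquisition plan
# (2 blocks x 2500 epochs per polarity = 10,000 epochs per condition).

#' Default acquisition plan
#'
#' @param blocks_per_polarity blocks recorded at each stimulus polarity
#' @param epochs_per_block epochs per block
#' @return a named list
#' @export
acquisition_plan <- function(blocks_per_polarity = 2, epochs_per_block = 2500) {
  stopifnot(blocks_per_polarity >= 1, epochs_per_block >= 1)
  list(blocks_per_polarity = as.integer(blocks_per_polarity),
       epochs_per_block = as.integer(epochs_per_block))
}

#' Container for labelled response epochs
#'
#' @param data numeric matrix, epochs x samples, in microvolts
#' @param fs_hz sampling rate (default 20000 Hz)
#' @param t0_ms time of the first sample relative to stimulus onset in
#'   acquisition time (negative = prestimulus baseline)
#' @param polarity per-epoch stimulus polarity (+1 / -1)
#' @param block per-epoch block id
#' @param condition condition label
#' @param subject subject id
#' @return an object of class `epoch_set`
#' @export
epoch_set <- function(data, fs_hz = 20000, t0_ms = -10,
                      polarity, block = rep(1L, nrow(data)),
                      condition = "unaided-quiet", subject = "s01") {
  data <- as.matrix(data)
  stopifnot(length(polarity) == nrow(data), all(polarity %in% c(-1, 1)),
            length(block) == nrow(data))
  structure(list(data = data, fs_hz = fs_hz, t0_ms = t0_ms,
                 polarity = as.integer(polarity), block = as.integer(block),
                 condition = condition, subject = subject),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s / %s: %d epochs x %d samples @ %g Hz, t0 = %g ms\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data), x$fs_hz,
              x$t0_ms))
  cat(sprintf("  polarity: %d (+1) / %d (-1); blocks: %s\n",
              sum(x$polarity == 1), sum(x$polarity == -1),
              paste(sort(unique(x$block)), collapse = ",")))
  invisible(x)
}

#' Time axis of an epoch set or averaged response
#' @param x an `epoch_set` or `averaged_response`
#' @return times in ms
#' @export
times_ms <- function(x) {
  n <- if (inherits(x, "epoch_set")) ncol(x$data) else length(x$waveform)
  time_axis(n, x$fs_hz, x$t0_ms)
}

.fw_cache <- new.env(parent = emptyenv())

#' Reference fundamental waveform of the stimulus (synchronous demodulation)
#'
#' The complex amplitude of the stimulus's F0-locked component, obtained by
#' heterodyning the (onset-zeroed) synthesized token with its own
#' instantaneous F0 phase and smoothing over about one cycle. The simulator
#' renders the envelope-following response as a delayed, scaled, phase-
#' rotated copy of this waveform, which is what a brainstem response that
#' follows the stimulus envelope at F0 looks like. Independent of the EMD
#' extraction used on the analysis side.
#'
#' @param spec a [stimulus_spec()]
#' @param fs_hz sampling rate of the rendered waveform (Hz)
#' @return list: `analytic` (complex vector, peak-normalised modulus 1),
#'   `t_ms` (stimulus-clock times), `fs_hz`
#' @export
reference_fundamental <- function(spec, fs_hz = 20000) {
  key <- paste(c(unlist(spec, use.names = FALSE), fs_hz), collapse = "|")
  if (!is.null(.fw_cache[[key]])) return(.fw_cache[[key]])
  stim <- resample_stimulus(synthesize_da(spec), fs_hz)
  x <- stim$samples
  t <- time_axis(length(x), fs_hz)
  voiced <- t >= spec$onset_burst_ms
  x[!voiced] <- 0
  ph <- numeric(length(x))
  ph[voiced] <- f0_phase(spec, t[voiced])
  z <- x * exp(-2i * pi * ph)
  # Gaussian smoothing, SD 1.5 ms: wide enough to reject the higher
  # harmonics, narrow enough to keep the envelope's temporal structure
  sd_n <- round(0.0015 * fs_hz)
  k <- stats::dnorm(seq(-3 * sd_n, 3 * sd_n), sd = sd_n)
  k <- k / sum(k)
  sm <- function(v) stats::filter(c(rep(0, 3 * sd_n), v, rep(0, 3 * sd_n)),
                                  k, sides = 2)[3 * sd_n + seq_along(v)]
  A <- complex(real = sm(Re(z)), imaginary = sm(Im(z)))
  a <- A * exp(2i * pi * ph)
  a[!voiced] <- 0
  a <- a / max(Mod(a))
  out <- list(analytic = a, t_ms = t, fs_hz = fs_hz)
  .fw_cache[[key]] <- out
  out
}

# Raised-cosine gate over [t_on, t_off] with `ramp` ms ramps.
rc_gate <- function(t_ms, t_on, t_off, ramp = 2.5) {
  g <- numeric(length(t_ms))
  g[t_ms >= t_on + ramp & t_ms <= t_off - ramp] <- 1
  up <- t_ms >= t_on & t_ms < t_on + ramp
  g[up] <- (1 - cos(pi * (t_ms[up] - t_on) / ramp)) / 2
  dn <- t_ms > t_off - ramp & t_ms <= t_off
  g[dn] <- (1 + cos(pi * (t_ms[dn] - (t_off - ramp)) / ramp)) / 2
  g
}

#' Render the deterministic clean response for a parameter set
#'
#' Sum of (a) Gaussian-windowed deflections (SD 0.5 ms) at each configured
#' peak latency and (b) an envelope-following response: a delayed
#' (`efr_latency_ms`), scaled copy of the stimulus's F0-locked fundamental
#' waveform ([reference_fundamental()]), whose instantaneous frequency
#' therefore follows the stimulus F0 track and which occupies the delayed
#' voiced period (~20-50 ms at the default latency). Because carrier and
#' envelope both ride on the latency, every feature of the response shifts
#' rigidly with its group delay, as a real envelope-following response's
#' does. `efr_amplitude_uv` is the envelope maximum. The default D, E, F
#' latencies of [default_params()] sit on this waveform's troughs, so the
#' transition-period morphology is self-consistent.
#'
#' @param params a `condition_params`
#' @param fs_hz sampling rate (Hz)
#' @param window `c(start, end)` of the rendered time axis, ms
#' @param delay_ms shift applied to the whole response (used to emulate
#'   acoustic propagation and hearing-aid processing delay in raw epochs)
#' @param peak_sd_ms width (SD) of the Gaussian deflections
#' @param efr_gate_ms optional explicit flat gate (`c(on, off)` ms,
#'   raised-cosine ramps) replacing the default Hann envelope over the
#'   delayed voiced period
#' @return numeric waveform in microvolts on `time_axis(window)`
#' @export
render_clean_response <- function(params, fs_hz = 20000, window = c(-10, 65),
                                  delay_ms = 0, peak_sd_ms = 0.5,
                                  efr_gate_ms = NULL) {
  n <- round((window[2] - window[1]) * fs_hz / 1000)
  t <- time_axis(n, fs_hz, window[1])
  lat <- params$peak_latencies_ms + delay_ms
  if (any(lat < window[1] | lat > window[2])) {
    stop("a configured peak latency falls outside the rendering window")
  }
  w <- numeric(n)
  for (k in seq_along(lat)) {
    w <- w + params$peak_amplitudes_uv[k] *
      exp(-(t - lat[k])^2 / (2 * peak_sd_ms^2))
  }
  if (params$efr_amplitude_uv > 0) {
    spec <- params$stim_spec
    fw <- reference_fundamental(spec, fs_hz)
    u <- t - delay_ms - params$efr_latency_ms
    osc <- stats::approx(fw$t_ms, Re(fw$analytic), xout = u,
                         yleft = 0, yright = 0)$y
    osc[u < 0 | u > spec$duration_ms | is.na(osc)] <- 0
    if (!is.null(efr_gate_ms)) {
      osc <- osc * rc_gate(t, efr_gate_ms[1] + delay_ms,
                           efr_gate_ms[2] + delay_ms)
    }
    w <- w + params$efr_amplitude_uv * osc
  }
  w
}

# Component that flips sign with stimulus polarity: a tone following the
# stimulus fine structure over the token's duration (a stand-in for stimulus
# artifact / cochlear microphonic), cancelled by alternating-polarity
# averaging.
polarity_locked_component <- function(params, fs_hz = 20000,
                                      window = c(-10, 65), delay_ms = 0,
                                      freq_hz = 1000) {
  n <- round((window[2] - window[1]) * fs_hz / 1000)
  t <- time_axis(n, fs_hz, window[1])
  u <- t - delay_ms
  on <- u >= 0 & u <= params$stim_spec$duration_ms
  out <- numeric(n)
  out[on] <- params$polarity_locked_amp_uv * sin(2 * pi * freq_hz * u[on] / 1000)
  out
}

# total acquisition-path delay emulated in raw epochs
acquisition_delay_ms <- function(params) {
  params$acoustic_delay_ms + if (is_aided(params$condition)) params$ha_delay_ms else 0
}

#' Generate a labelled set of simulated epochs
#'
#' Each epoch is the clean response (shifted by the emulated acoustic and,
#' for aided conditions, hearing-aid processing delay), plus the
#' polarity-locked component multiplied by the epoch's stimulus polarity,
#' plus white Gaussian EEG noise, plus -- with probability `artifact_rate` --
#' an injected transient exceeding 30 uV. Fully reproducible under `seed`.
#'
#' @param params a `condition_params`
#' @param plan an [acquisition_plan()]
#' @param seed integer seed
#' @param fs_hz sampling rate (Hz)
#' @param window epoch window relative to acquisition-time stimulus onset, ms
#' @param subject subject id label
#' @param noise_model `"white"` (default) or `"pink"` (1/f-shaped)
#' @return an [epoch_set()]
#' @export
generate_epochs <- function(params, plan = acquisition_plan(), seed = 1L,
                            fs_hz = 20000, window = c(-10, 65),
                            subject = "s01", noise_model = c("white", "pink")) {
  noise_model <- match.arg(noise_model)
  delay <- acquisition_delay_ms(params)
  clean <- render_clean_response(params, fs_hz, window, delay_ms = delay)
  locked <- polarity_locked_component(params, fs_hz, window, delay_ms = delay)
  n_samp <- length(clean)
  per_pol <- plan$blocks_per_polarity * plan$epochs_per_block
  n_ep <- 2L * per_pol
  polarity <- rep(c(1L, -1L), each = per_pol)
  block <- rep(rep(seq_len(plan$blocks_per_polarity),
                   each = plan$epochs_per_block), times = 2)

  set.seed(derive_seed(seed, subject, params$condition))
  data <- matrix(stats::rnorm(n_ep * n_samp, sd = params$noise_sd_uv),
                 nrow = n_ep, ncol = n_samp)
  if (noise_model == "pink" && params$noise_sd_uv > 0) {
    data <- t(apply(data, 1, pink_shape, fs_hz = fs_hz))
    data <- data * (params$noise_sd_uv / stats::sd(as.vector(data)))
  }
  data <- data + rep(clean, each = n_ep) +
    outer(as.numeric(polarity), locked)
  if (params$artifact_rate > 0) {
    hit <- which(stats::runif(n_ep) < params$artifact_rate)
    t <- time_axis(n_samp, fs_hz, window[1])
    for (i in hit) {
      tc <- stats::runif(1, window[1] + 5, window[2] - 5)
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 40, 80)
      data[i, ] <- data[i, ] + amp * exp(-(t - tc)^2 / (2 * 2^2))
    }
  }
  epoch_set(data, fs_hz = fs_hz, t0_ms = window[1], polarity = polarity,
            block = block, condition = params$condition, subject = subject)
}

# 1/f amplitude shaping of a white-noise vector (optional noise model)
pink_shape <- function(x, fs_hz) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1)) * fs_hz / n
  f <- pmin(f, fs_hz - f + fs_hz / n)
  Re(stats::fft(X / sqrt(f / min(f)), inverse = TRUE)) / n
}

#' Simulate a multi-subject study with known ground truth
#'
#' Per-subject parameters jitter around [default_params()]: a common latency
#' shift (SD 0.3 ms), a common amplitude scale (log-normal, SD(log) 0.15),
#' EFR latency jitter (SD 0.3 ms), and subject-specific effect sizes
#' (aided latency advance ~ N(1.0, 0.15), aided gain ~ N(1.3, 0.1), noise F0
#' delay ~ N(1.7, 0.25), truncated away from sign reversal). The same
#' subject-level draw feeds all four conditions, mirroring the paired design.
#'
#' @param n_subjects number of simulated subjects
#' @param conditions condition labels to simulate (default: all four)
#' @param seed master seed; all subject/condition randomness derives from it
#' @param plan an [acquisition_plan()]
#' @param base_params optional `condition_params` template replacing the
#'   unaided-quiet defaults (effect-size fields included)
#' @param jitter named list overriding jitter SDs
#'   (`lat_shift`, `amp_sdlog`, `efr_lat`, `advance`, `gain`, `noise_delay`);
#'   set all to 0 for identical subjects
#' @return list with `epoch_sets` (list of [epoch_set()]s, one per
#'   subject x condition) and `ground_truth` (registry keyed
#'   `"<subject>/<condition>"`, each entry the true `condition_params`)
#' @export
generate_study <- function(n_subjects, conditions = CONDITIONS, seed = 1L,
                           plan = acquisition_plan(), base_params = NULL,
                           jitter = list()) {
  gt <- study_ground_truth(n_subjects, conditions = conditions, seed = seed,
                           base_params = base_params, jitter = jitter)
  epoch_sets <- lapply(names(gt), function(key) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    study_epochs(gt, parts[1], parts[2], plan = plan, seed = seed)
  })
  names(epoch_sets) <- names(gt)
  list(epoch_sets = epoch_sets, ground_truth = gt)
}

#' Draw the per-subject ground-truth parameter registry of a study
#'
#' The jitter model described in [generate_study()], without generating any
#' epochs; [study_epochs()] materialises a single subject x condition cell,
#' which keeps full-size studies within memory.
#'
#' @inheritParams generate_study
#' @return named list keyed `"<subject>/<condition>"` of `condition_params`
#' @export
study_ground_truth <- function(n_subjects, conditions = CONDITIONS, seed = 1L,
                               base_params = NULL, jitter = list()) {
  stopifnot(n_subjects >= 1)
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  jit <- utils::modifyList(
    list(lat_shift = 0.3, amp_sdlog = 0.15, efr_lat = 0.3,
         advance = 0.15, gain = 0.1, noise_delay = 0.25),
    jitter
  )
  template <- base_params %||% default_params("unaided-quiet", seed = seed)
  ground_truth <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    set.seed(derive_seed(seed, "subject-params", s))
    base <- template
    base$peak_latencies_ms <- base$peak_latencies_ms +
      stats::rnorm(1, 0, jit$lat_shift)
    base$peak_amplitudes_uv <- base$peak_amplitudes_uv *
      exp(stats::rnorm(1, 0, jit$amp_sdlog))
    base$efr_amplitude_uv <- base$efr_amplitude_uv *
      exp(stats::rnorm(1, 0, jit$amp_sdlog))
    base$efr_latency_ms <- base$efr_latency_ms + stats::rnorm(1, 0, jit$efr_lat)
    base$aided_latency_advance_ms <-
      max(min(0.2, template$aided_latency_advance_ms),
          base$aided_latency_advance_ms + stats::rnorm(1, 0, jit$advance))
    base$aided_gain <- max(min(1.02, template$aided_gain),
                           base$aided_gain + stats::rnorm(1, 0, jit$gain))
    base$noise_f0_delay_ms <-
      max(min(0.3, template$noise_f0_delay_ms),
          base$noise_f0_delay_ms + stats::rnorm(1, 0, jit$noise_delay))
    for (cond in conditions) {
      ground_truth[[paste0(sid, "/", cond)]] <- condition_variant(base, cond)
    }
  }
  ground_truth
}

#' Generate the epochs of one study cell
#'
#' @param ground_truth registry from [study_ground_truth()]
#' @param subject,condition cell key
#' @param plan an [acquisition_plan()]
#' @param seed the study's master seed (the cell's own seed is derived)
#' @return an [epoch_set()]
#' @export
study_epochs <- function(ground_truth, subject, condition,
                         plan = acquisition_plan(), seed = 1L) {
  p <- ground_truth[[paste0(subject, "/", condition)]]
  s <- as.integer(sub("^s", "", subject))
  generate_epochs(p, plan = plan,
                  seed = derive_seed(seed, "epochs", s, condition),
                  subject = subject)
}

#' Write an epoch set as CSV plus JSON metadata sidecar
#'
#' One row per epoch with `polarity` and `block` label columns followed by
#' sample columns; sampling metadata goes to `<path>.json`. Intended for
#' small fixtures -- full-size sets are large.
#'
#' @param epochs an [epoch_set()]
#' @param path output `.csv` path
#' @return `path`, invisibly
#' @export
write_epoch_csv <- function(epochs, path) {
  df <- data.frame(polarity = epochs$polarity, block = epochs$block,
                   epochs$data)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs_hz = epochs$fs_hz, t0_ms = epochs$t0_ms,
         condition = epochs$condition, subject = epochs$subject,
         n_epochs = nrow(epochs$data), n_samples = ncol(epochs$data)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read an epoch set written by [write_epoch_csv()]
#' @param path `.csv` path
#' @return an [epoch_set()]
#' @export
read_epoch_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  epoch_set(as.matrix(df[, -(1:2)]), fs_hz = meta$fs_hz, t0_ms = meta$t0_ms,
            polarity = df$polarity, block = df$block,
            condition = meta$condition, subject = meta$subject)
}
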