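# Orchestration: simulate -> reject -> average -> filter -> correct ->
# detect/measure peaks -> F0 encoding, across subjects and conditions, with
# a tidy long-format results table and parameter-recovery evaluation
# against the simulator's ground truth.

#' Default pipeline configuration
#'
#' @param reject_threshold_uv artifact rejection threshold (uV)
#' @param peak_lowpass_hz offline low-pass for peak analysis (Hz)
#' @param f0_lowpass_hz low-pass for the F0-encoding path (Hz)
#' @param acoustic_ms,ha_delay_ms time corrections (ms)
#' @param n_boot bootstrap replicates for the noise-floor band
#' @param alpha 1 - confidence of the noise-floor band
#' @param n_segments segments for the Hotelling presence test
#' @param windows peak search windows, see [default_peak_windows()]
#' @param f0_zero_first_ms,f0_end_ms response trimming for the F0 path (ms)
#' @param f0_lag_window_ms lag search window for the F0 envelope peak (ms)
#' @return named list of parameters
#' @export
pipeline_config <- function(reject_threshold_uv = 30,
                            peak_lowpass_hz = 1500,
                            f0_lowpass_hz = 300,
                            acoustic_ms = 3.3, ha_delay_ms = 7.9,
                            n_boot = 500, alpha = 0.05, n_segments = 10,
                            windows = default_peak_windows(),
                            f0_zero_first_ms = 20, f0_end_ms = 50,
                            f0_lag_window_ms = c(0, 20)) {
  as.list(environment())
}

#' Run the full analysis on one condition's epochs
#'
#' Executes reject -> alternating average -> zero-phase low-pass -> time
#' corrections -> bootstrap noise floor -> peak picking, two-criterion
#' detection and amplitude measurement, plus the F0-encoding analysis
#' (complex cross-correlation + Hotelling presence test).
#'
#' @param epochs an [epoch_set()] (raw)
#' @param f0 an `f0_waveform` extracted from the stimulus
#' @param config a [pipeline_config()]
#' @param seed seed for the bootstrap sign flips
#' @return list: `peaks` (data.frame with latency, amplitude, criteria per
#'   peak), `f0` (`f0_encoding_result`), `avg` (`averaged_response`),
#'   `band`, `n_rejected`
#' @export
run_condition <- function(epochs, f0, config = pipeline_config(), seed = 1L) {
  aided <- is_aided(epochs$condition)
  rej <- reject_artifacts(epochs, config$reject_threshold_uv)
  avg <- alternating_average(rej$epochs)
  avg <- filter_response(avg, low_hz = config$peak_lowpass_hz)
  avg <- apply_time_corrections(avg, acoustic_ms = config$acoustic_ms,
                                ha_delay_ms = config$ha_delay_ms,
                                aided = aided)
  band <- bootstrap_noise_floor(rej$epochs, n_boot = config$n_boot,
                                alpha = config$alpha,
                                seed = derive_seed(seed, "boot",
                                                   epochs$subject,
                                                   epochs$condition),
                                low_hz = config$peak_lowpass_hz)
  peaks <- pick_peaks(avg, windows = config$windows)
  peaks <- assess_detection(avg, band, peaks)
  peaks <- measure_amplitudes(avg, peaks)
  corrections <- config$acoustic_ms + if (aided) config$ha_delay_ms else 0
  f0res <- f0_encode(rej$epochs, f0, corrections_ms = corrections,
                     n_segments = config$n_segments,
                     zero_first_ms = config$f0_zero_first_ms,
                     end_ms = config$f0_end_ms,
                     lowpass_hz = config$f0_lowpass_hz,
                     lag_window_ms = config$f0_lag_window_ms)
  list(peaks = peaks, f0 = f0res, avg = avg, band = band,
       n_rejected = rej$n_rejected)
}

condition_rows <- function(subject, condition, res) {
  pk <- res$peaks
  rbind(
    data.frame(subject = subject, condition = condition,
               measure = paste0("latency:", pk$peak),
               value = ifelse(pk$detected, pk$latency_ms, NA_real_),
               detected = pk$detected, units = "ms"),
    data.frame(subject = subject, condition = condition,
               measure = paste0("amplitude:",
                                ifelse(pk$peak == "V", "VA", pk$peak)),
               value = ifelse(pk$detected, pk$amplitude_uv, NA_real_),
               detected = pk$detected, units = "uV")[pk$peak != "A", ],
    data.frame(subject = subject, condition = condition,
               measure = c("f0_latency", "f0_amplitude"),
               value = if (res$f0$present) {
                 c(res$f0$latency_ms, res$f0$amplitude)
               } else c(NA_real_, NA_real_),
               detected = res$f0$present,
               units = c("ms", "uV"))
  )
}

#' Run a simulated multi-subject study end to end
#'
#' Simulates `n_subjects` x 4 conditions with [generate_study()], analyses
#' every condition with [run_condition()], and compares the estimated
#' condition contrasts with the simulated ground truth.
#'
#' @param n_subjects number of subjects
#' @param seed master seed (simulation + bootstrap)
#' @param plan an [acquisition_plan()]
#' @param config a [pipeline_config()]
#' @param conditions conditions to simulate
#' @param base_params,jitter forwarded to [generate_study()]
#' @param stimulus optional pre-built `stimulus` (at 20 kHz); default
#'   synthesizes and resamples the standard token
#' @return list: `results` (long-format data.frame: subject, condition,
#'   measure, value, detected, units), `recovery` (data.frame of contrast
#'   estimates vs ground truth), `ground_truth`
#' @export
run_study <- function(n_subjects = 20, seed = 1L, plan = acquisition_plan(),
                      config = pipeline_config(), conditions = CONDITIONS,
                      base_params = NULL, jitter = list(), stimulus = NULL) {
  stim <- stimulus %||% resample_stimulus(synthesize_da(), 20000)
  f0 <- extract_fundamental(stim)
  gt <- study_ground_truth(n_subjects, conditions = conditions, seed = seed,
                           base_params = base_params, jitter = jitter)
  rows <- list()
  for (key in names(gt)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    es <- study_epochs(gt, parts[1], parts[2], plan = plan, seed = seed)
    res <- run_condition(es, f0, config = config, seed = seed)
    rows[[key]] <- condition_rows(es$subject, es$condition, res)
    rm(es)
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  recovery <- recovery_report(results, gt)
  list(results = results, recovery = recovery, ground_truth = gt)
}

value_of <- function(results, subject, condition, measure) {
  v <- results$value[results$subject == subject &
                       results$condition == condition &
                       results$measure == measure]
  if (length(v) == 1) v else NA_real_
}

#' Compare estimated condition contrasts with simulated ground truth
#'
#' For each measure, the aided - unaided and noise - quiet contrasts are
#' averaged within subject (over the other factor) and across subjects,
#' using only subject/condition cells where the measure was detected in
#' both conditions being contrasted. True contrast values come from the
#' per-subject ground-truth registry.
#'
#' @param results long-format results from [run_study()]
#' @param ground_truth registry from [generate_study()]
#' @return data.frame: `parameter`, `estimate`, `truth`, `bias`, `rmse`
#'   (across subjects), `sign_consistent`, `n_subjects_used`
#' @export
recovery_report <- function(results, ground_truth) {
  subjects <- unique(results$subject)
  gt_of <- function(subject) ground_truth[[paste0(subject, "/unaided-quiet")]]

  per_subject <- function(est_fun, truth_fun) {
    est <- vapply(subjects, est_fun, numeric(1))
    tru <- vapply(subjects, function(s) truth_fun(gt_of(s)), numeric(1))
    ok <- is.finite(est) & is.finite(tru)
    data.frame(estimate = mean(est[ok]), truth = mean(tru[ok]),
               bias = mean(est[ok] - tru[ok]),
               rmse = sqrt(mean((est[ok] - tru[ok])^2)),
               sign_consistent = if (all(tru[ok] == 0)) NA else
                 sign(mean(est[ok])) == sign(mean(tru[ok])),
               n_subjects_used = sum(ok))
  }

  paired_mean <- function(s, measure, a_conds, b_conds) {
    d <- mapply(function(a, b) {
      va <- value_of(results, s, a, measure)
      vb <- value_of(results, s, b, measure)
      va - vb
    }, a_conds, b_conds)
    if (all(!is.finite(d))) NA_real_ else mean(d, na.rm = TRUE)
  }

  out <- list()
  # aided latency advance: mean over the six peaks of (unaided - aided)
  out[["aided_latency_advance_ms"]] <- per_subject(
    function(s) {
      d <- vapply(PEAKS, function(pk) {
        paired_mean(s, paste0("latency:", pk),
                    c("unaided-quiet", "unaided-noise"),
                    c("aided-quiet", "aided-noise"))
      }, numeric(1))
      mean(d, na.rm = TRUE)
    },
    function(gt) gt$aided_latency_advance_ms
  )
  # aided amplitude gain, as fractional increase (ratio - 1)
  out[["aided_amplitude_gain"]] <- per_subject(
    function(s) {
      r <- vapply(c("VA", "D", "E", "F", "O"), function(pk) {
        m <- paste0("amplitude:", pk)
        num <- mean(c(value_of(results, s, "aided-quiet", m),
                      value_of(results, s, "aided-noise", m)), na.rm = TRUE)
        den <- mean(c(value_of(results, s, "unaided-quiet", m),
                      value_of(results, s, "unaided-noise", m)), na.rm = TRUE)
        num / den
      }, numeric(1))
      mean(r, na.rm = TRUE) - 1
    },
    function(gt) gt$aided_gain - 1
  )
  # noise-induced F0 encoding delay (noise - quiet)
  out[["noise_f0_delay_ms"]] <- per_subject(
    function(s) paired_mean(s, "f0_latency",
                            c("aided-noise", "unaided-noise"),
                            c("aided-quiet", "unaided-quiet")),
    function(gt) gt$noise_f0_delay_ms
  )
  # background effect on peak latencies (truth: none)
  out[["noise_peak_latency_shift_ms"]] <- per_subject(
    function(s) {
      d <- vapply(PEAKS, function(pk) {
        paired_mean(s, paste0("latency:", pk),
                    c("aided-noise", "unaided-noise"),
                    c("aided-quiet", "unaided-quiet"))
      }, numeric(1))
      mean(d, na.rm = TRUE)
    },
    function(gt) 0
  )
  # aided F0 amplitude gain, as fractional increase (ratio - 1)
  out[["aided_f0_gain"]] <- per_subject(
    function(s) {
      num <- mean(c(value_of(results, s, "aided-quiet", "f0_amplitude"),
                    value_of(results, s, "aided-noise", "f0_amplitude")),
                  na.rm = TRUE)
      den <- mean(c(value_of(results, s, "unaided-quiet", "f0_amplitude"),
                    value_of(results, s, "unaided-noise", "f0_amplitude")),
                  na.rm = TRUE)
      num / den - 1
    },
    function(gt) gt$aided_gain - 1
  )
  cbind(data.frame(parameter = names(out)),
        do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Per-condition detection summary
#'
#' Percentage of peaks detected (over peaks x subjects) and of F0 encodings
#' declared present, per condition.
#'
#' @param results long-format results from [run_study()]
#' @return data.frame: `condition`, `peaks_detected_pct`, `f0_present_pct`
#' @export
detection_summary <- function(results) {
  stopifnot(nrow(results) > 0)
  conds <- unique(results$condition)
  out <- lapply(conds, function(cond) {
    pk <- results[results$condition == cond &
                    grepl("^latency:", results$measure), ]
    f0 <- results[results$condition == cond & results$measure == "f0_latency", ]
    data.frame(condition = cond,
               peaks_detected_pct = 100 * mean(pk$detected),
               f0_present_pct = 100 * mean(f0$detected))
  })
  do.call(rbind, out)
}

#' Nominal stimulus presentation rate
#'
#' @param duration_ms stimulus duration (ms)
#' @param isi_ms interstimulus interval (ms)
#' @param digits rounding of the reported rate (default 1, the convention
#'   for reporting e.g. 9.1/s)
#' @return presentations per second
#' @export
presentation_rate <- function(duration_ms = 40, isi_ms = 70, digits = 1) {
  round(1000 / (duration_ms + isi_ms), digits)
}

#' Epochs per condition implied by an acquisition plan
#' @param plan an [acquisition_plan()]
#' @return total epoch count (both polarities)
#' @export
epochs_per_condition <- function(plan = acquisition_plan()) {
  2L * plan$blocks_per_polarity * plan$epochs_per_block
}
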