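# Detection and measurement of speech-ABR peaks V, A, D, E, F, O with the
# two-criterion rule: (a) the averaged waveform exceeds a bootstrap 95%
# noise-floor band at the peak, and (b) the peak repeats with the same sign
# in both subaverages.

#' Bootstrap EEG noise-floor confidence band
#'
#' Noise-floor replicates are built by averaging the epochs after
#' independent random sign flips, which destroys all phase-locked content
#' while preserving the noise statistics of the average. Each replicate is
#' de-meaned and optionally low-pass filtered so the band lives in the same
#' processing domain as the averaged response it is compared against. The
#' band is the pointwise (alpha/2, 1 - alpha/2) quantile envelope across
#' replicates.
#'
#' @param epochs an [epoch_set()] (post artifact rejection)
#' @param n_boot number of bootstrap replicates (default 1000; fewer than
#'   100 triggers a warning)
#' @param alpha 1 - confidence level (default 0.05, a 95% band)
#' @param seed integer seed for the sign flips
#' @param low_hz optional zero-phase low-pass applied to every replicate,
#'   matching the filtering of the averaged response
#' @return object of class `noise_floor_band`: `lower`, `upper` (uV per
#'   time point), `alpha`, `n_boot`, `seed`, `fs_hz`, `t0_ms`
#' @export
bootstrap_noise_floor <- function(epochs, n_boot = 1000, alpha = 0.05,
                                  seed = 1L, low_hz = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), nrow(epochs$data) >= 2)
  if (n_boot < 100) warning("n_boot < 100 gives unstable quantile estimates")
  n_ep <- nrow(epochs$data)
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_boot * n_ep, replace = TRUE),
                  nrow = n_boot)
  reps <- (flips %*% epochs$data) / n_ep
  reps <- reps - rowMeans(reps)
  if (!is.null(low_hz)) {
    reps <- filter_waveform(reps, epochs$fs_hz, low_hz = low_hz)
  }
  qs <- apply(reps, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(lower = qs[1, ], upper = qs[2, ], alpha = alpha,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         fs_hz = epochs$fs_hz, t0_ms = epochs$t0_ms,
         replicates = reps),
    class = "noise_floor_band"
  )
}

#' @export
print.noise_floor_band <- function(x, ...) {
  cat(sprintf(
    "<noise_floor_band> %d points, %d replicates, %.0f%% confidence\n",
    length(x$lower), x$n_boot, 100 * (1 - x$alpha)))
  invisible(x)
}

#' Default peak search windows (ms, corrected time)
#'
#' Conventional latency ranges for the 40 ms [da] response; every reported
#' latency should be interpreted relative to its search window.
#'
#' @return named list of `c(lo, hi)` windows
#' @export
default_peak_windows <- function() {
  list(V = c(6, 11), A = c(8, 14), D = c(20, 28),
       E = c(28, 36), F = c(37, 46), O = c(46, 56))
}

sample_index <- function(resp, t_target_ms) {
  i <- round((t_target_ms - resp$t0_ms) * resp$fs_hz / 1000) + 1
  as.integer(pmax(1, pmin(length(resp$waveform), i)))
}

#' Automated peak picking within latency windows
#'
#' Wave V is the maximum within its window; A, D, E, F, O are minima within
#' theirs; ties break to the earliest latency. Extrema landing on a window
#' edge are flagged (`edge_hit`) as untrustworthy.
#'
#' @param avg an `averaged_response` (corrected time axis)
#' @param windows named list of latency windows as in
#'   [default_peak_windows()]
#' @return data.frame: `peak`, `latency_ms`, `value_uv`, `edge_hit`
#' @export
pick_peaks <- function(avg, windows = default_peak_windows()) {
  stopifnot(inherits(avg, "averaged_response"))
  t <- times_ms(avg)
  out <- lapply(names(windows), function(pk) {
    w <- windows[[pk]]
    if (w[1] >= w[2]) stop("degenerate window for peak ", pk)
    idx <- which(t >= w[1] & t <= w[2])
    if (length(idx) == 0) stop("window for peak ", pk,
                               " lies outside the epoch support")
    seg <- avg$waveform[idx]
    j <- if (pk == "V") which.max(seg) else which.min(seg)  # earliest tie
    data.frame(peak = pk, latency_ms = t[idx[j]], value_uv = seg[j],
               edge_hit = j == 1L || j == length(seg))
  })
  do.call(rbind, out)
}

#' Apply the two detection criteria to candidate peaks
#'
#' `bootstrap_pass`: the candidate extremum exceeds, on the correct side,
#' what the noise floor produces for the *extremum over the same search
#' window* -- for wave V the `1 - alpha` quantile of the window maximum
#' across the sign-flip replicates, for the negative peaks the `alpha`
#' quantile of the window minimum. Comparing the picked extremum against a
#' pointwise band would ignore that the extremum was selected over the
#' whole window and mis-state the confidence level; the window-extremum
#' reference keeps the per-window false-positive rate at `alpha`.
#' `repeatable`: within +/- `repeat_tol_ms` of the candidate, both
#' subaverages show a dominant deflection of the peak's sign (the same-sign
#' extremum exceeds the opposite-sign extremum in magnitude). `detected`
#' requires both.
#'
#' @param avg an `averaged_response`
#' @param band a `noise_floor_band` computed from the same epochs
#' @param candidates data.frame from [pick_peaks()]
#' @param windows the search windows the candidates came from
#' @param repeat_tol_ms tolerance of the repeatability check (default 1 ms)
#' @return `candidates` with columns `bootstrap_pass`, `repeatable`,
#'   `detected` appended
#' @export
assess_detection <- function(avg, band, candidates,
                             windows = default_peak_windows(),
                             repeat_tol_ms = 1) {
  stopifnot(inherits(avg, "averaged_response"),
            inherits(band, "noise_floor_band"))
  t <- times_ms(avg)
  res <- candidates
  res$bootstrap_pass <- NA
  res$repeatable <- NA
  for (r in seq_len(nrow(res))) {
    pk <- res$peak[r]
    i <- sample_index(avg, res$latency_ms[r])
    positive <- pk == "V"
    w <- windows[[pk]]
    widx <- which(t >= w[1] & t <= w[2])
    if (positive) {
      ext <- apply(band$replicates[, widx, drop = FALSE], 1, max)
      res$bootstrap_pass[r] <-
        avg$waveform[i] > stats::quantile(ext, 1 - band$alpha, names = FALSE)
    } else {
      ext <- apply(band$replicates[, widx, drop = FALSE], 1, min)
      res$bootstrap_pass[r] <-
        avg$waveform[i] < stats::quantile(ext, band$alpha, names = FALSE)
    }
    idx <- which(abs(t - res$latency_ms[r]) <= repeat_tol_ms)
    res$repeatable[r] <- all(apply(avg$subaverages[, idx, drop = FALSE], 1,
                                   function(seg) {
                                     if (positive) max(seg) > -min(seg)
                                     else -min(seg) > max(seg)
                                   }))
  }
  res$detected <- res$bootstrap_pass & res$repeatable
  res
}

#' Peak-to-trough amplitude measurement
#'
#' The V amplitude is the classic V-to-A drop (`value(V) - value(A)`,
#' reported on the V row). For each negative peak D, E, F, O the amplitude is
#' measured from the highest point between the previous labelled trough (or
#' the start of the D search window for D) and the trough itself, down to the
#' trough. A flat zero waveform yields zero amplitudes.
#'
#' @param avg an `averaged_response`
#' @param peaks data.frame from [pick_peaks()] /
#'   [assess_detection()] containing all six peaks
#' @return `peaks` with column `amplitude_uv` appended (`NA` on the A row)
#' @export
measure_amplitudes <- function(avg, peaks) {
  stopifnot(all(PEAKS %in% peaks$peak))
  t <- times_ms(avg)
  lat <- stats::setNames(peaks$latency_ms, peaks$peak)
  val <- stats::setNames(peaks$value_uv, peaks$peak)
  peaks$amplitude_uv <- NA_real_
  peaks$amplitude_uv[peaks$peak == "V"] <- val[["V"]] - val[["A"]]
  prev <- c(D = "A", E = "D", F = "E", O = "F")
  for (pk in names(prev)) {
    lo <- lat[[prev[[pk]]]]
    hi <- lat[[pk]]
    idx <- which(t > lo & t < hi)
    if (length(idx) == 0) stop("no samples between ", prev[[pk]], " and ", pk,
                               " to search for the preceding maximum")
    peaks$amplitude_uv[peaks$peak == pk] <- max(avg$waveform[idx]) - val[[pk]]
  }
  peaks
}
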