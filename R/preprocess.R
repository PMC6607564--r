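# From raw labelled epochs to corrected, filtered averaged responses:
# amplitude-based artifact rejection, alternating-polarity block averaging
# with de-meaned subaverages, zero-phase low-pass filtering, and acoustic /
# hearing-aid time corrections.

#' Reject epochs containing high-amplitude activity
#'
#' Drops every epoch whose maximum absolute amplitude exceeds the threshold
#' (boundary kept: an epoch peaking exactly at the threshold is retained),
#' emulating online artifact rejection at 30 uV.
#'
#' @param epochs an [epoch_set()]
#' @param threshold_uv rejection threshold (uV, default 30)
#' @return list with `epochs` (retained set), `n_rejected`, and
#'   `n_rejected_by_polarity`
#' @export
reject_artifacts <- function(epochs, threshold_uv = 30) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold_uv
  if (!any(keep)) stop("all epochs rejected at ", threshold_uv, " uV")
  out <- epochs
  out$data <- epochs$data[keep, , drop = FALSE]
  out$polarity <- epochs$polarity[keep]
  out$block <- epochs$block[keep]
  list(
    epochs = out,
    n_rejected = sum(!keep),
    n_rejected_by_polarity = c(
      pos = sum(!keep & epochs$polarity == 1),
      neg = sum(!keep & epochs$polarity == -1)
    )
  )
}

de_mean <- function(x) x - mean(x)

#' Alternating-polarity averaging with de-meaned subaverages
#'
#' Each block is averaged per polarity; the b-th positive-polarity block mean
#' is then averaged with the b-th negative-polarity block mean, giving one
#' alternating-polarity subaverage per block pair, each baseline-corrected by
#' subtracting its full-epoch mean. The full average is the mean of the
#' subaverages. Averaging opposite polarities with equal weight cancels any
#' component that flips sign with stimulus polarity (stimulus artifact,
#' cochlear microphonic) regardless of retained epoch counts.
#'
#' @param epochs an [epoch_set()] containing both polarities
#' @return an object of class `averaged_response`: `waveform` (uV),
#'   `subaverages` (matrix, one per row), `fs_hz`, `t0_ms`, `n_epochs_used`,
#'   `corrections_applied_ms` (0 until [apply_time_corrections()]),
#'   `filters_applied`, `condition`, `subject`
#' @export
alternating_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(unique(epochs$polarity)) < 2) {
    stop("alternating-polarity averaging needs both stimulus polarities")
  }
  blocks <- sort(unique(epochs$block))
  subs <- t(vapply(blocks, function(b) {
    mp <- colMeans(epochs$data[epochs$block == b & epochs$polarity == 1, ,
                               drop = FALSE])
    mn <- colMeans(epochs$data[epochs$block == b & epochs$polarity == -1, ,
                               drop = FALSE])
    de_mean((mp + mn) / 2)
  }, numeric(ncol(epochs$data))))
  structure(
    list(waveform = colMeans(subs), subaverages = subs,
         fs_hz = epochs$fs_hz, t0_ms = epochs$t0_ms,
         n_epochs_used = nrow(epochs$data),
         corrections_applied_ms = 0,
         filters_applied = character(0),
         condition = epochs$condition, subject = epochs$subject),
    class = "averaged_response"
  )
}

#' @export
print.averaged_response <- function(x, ...) {
  cat(sprintf("<averaged_response> %s / %s: %d samples @ %g Hz, %d epochs\n",
              x$subject, x$condition, length(x$waveform), x$fs_hz,
              x$n_epochs_used))
  cat(sprintf("  t0 = %g ms (corrections applied: %g ms); filters: %s\n",
              x$t0_ms, x$corrections_applied_ms,
              if (length(x$filters_applied)) paste(x$filters_applied,
                                                   collapse = "; ") else "none"))
  invisible(x)
}

#' Zero-phase filter an averaged response (and its subaverages)
#'
#' @param resp an `averaged_response`
#' @param low_hz,high_hz cutoffs; the offline convention is a 1500 Hz
#'   low-pass for peak analysis and a 300 Hz low-pass for F0 encoding
#' @return the filtered `averaged_response`
#' @export
filter_response <- function(resp, low_hz = 1500, high_hz = NULL) {
  stopifnot(inherits(resp, "averaged_response"))
  resp$waveform <- filter_waveform(resp$waveform, resp$fs_hz, low_hz, high_hz)
  resp$subaverages <- filter_waveform(resp$subaverages, resp$fs_hz, low_hz,
                                      high_hz)
  resp$filters_applied <- c(
    resp$filters_applied,
    paste0("zero-phase FIR",
           if (!is.null(high_hz)) paste0(" high-pass ", high_hz, " Hz"),
           if (!is.null(low_hz)) paste0(" low-pass ", low_hz, " Hz"))
  )
  resp
}

#' Apply acoustic and hearing-aid time corrections
#'
#' Shifts the time axis earlier by the loudspeaker propagation delay
#' (distance / speed of sound, 3.3 ms for the standard setup) and, for aided
#' recordings, additionally by the hearing-aid processing delay (7.9 ms).
#' The shift relabels the axis rather than moving samples, so no data are
#' truncated. Applying corrections twice is an error.
#'
#' @param resp an `averaged_response`
#' @param acoustic_ms propagation correction (ms)
#' @param ha_delay_ms hearing-aid processing correction (ms)
#' @param aided logical: apply the hearing-aid correction?
#' @return the corrected `averaged_response`
#' @export
apply_time_corrections <- function(resp, acoustic_ms = 3.3, ha_delay_ms = 7.9,
                                   aided = FALSE) {
  stopifnot(inherits(resp, "averaged_response"))
  if (resp$corrections_applied_ms != 0) {
    stop("time corrections already applied (", resp$corrections_applied_ms,
         " ms)")
  }
  total <- acoustic_ms + if (aided) ha_delay_ms else 0
  resp$t0_ms <- resp$t0_ms - total
  resp$corrections_applied_ms <- total
  resp
}

#' Write an averaged response as CSV (time_ms, amplitude_uv) + JSON sidecar
#' @param resp an `averaged_response`
#' @param path output `.csv` path
#' @return `path`, invisibly
#' @export
write_averaged_response <- function(resp, path) {
  utils::write.csv(
    data.frame(time_ms = times_ms(resp), amplitude_uv = resp$waveform),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(fs_hz = resp$fs_hz, t0_ms = resp$t0_ms,
         n_epochs_used = resp$n_epochs_used,
         corrections_applied_ms = resp$corrections_applied_ms,
         filters_applied = resp$filters_applied,
         condition = resp$condition, subject = resp$subject),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}
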