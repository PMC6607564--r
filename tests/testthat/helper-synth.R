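# Shared fixtures, built in code. The stimulus and its extracted fundamental
# are comparatively expensive (EMD on ten concatenated tokens), so they are
# computed once per test run.

test_cache <- new.env(parent = emptyenv())

test_stimulus <- function() {
  if (is.null(test_cache$stim)) {
    test_cache$stim <- resample_stimulus(synthesize_da(), 20000)
  }
  test_cache$stim
}

test_f0 <- function() {
  if (is.null(test_cache$f0)) {
    test_cache$f0 <- extract_fundamental(test_stimulus())
  }
  test_cache$f0
}

# wrap a bare waveform as an averaged response on the corrected time axis
as_avg <- function(w, fs_hz = 20000, t0_ms = -10, condition = "unaided-quiet") {
  structure(
    list(waveform = w, subaverages = matrix(w, nrow = 1), fs_hz = fs_hz,
         t0_ms = t0_ms, n_epochs_used = 1L, corrections_applied_ms = 0,
         filters_applied = character(0), condition = condition,
         subject = "s01"),
    class = "averaged_response"
  )
}

# parameters with every stochastic nuisance switched off
quiet_params <- function(condition = "unaided-quiet", ...) {
  p <- default_params(condition)
  p$noise_sd_uv <- 0
  p$artifact_rate <- 0
  p$polarity_locked_amp_uv <- 0
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}
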