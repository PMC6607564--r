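test_that("noise floor band collapses for silent epochs and flags strong peaks", {
  es0 <- epoch_set(matrix(0, 10, 100), polarity = rep(c(1L, -1L), 5))
  band0 <- bootstrap_noise_floor(es0, n_boot = 200, seed = 1)
  expect_true(all(band0$lower == 0) && all(band0$upper == 0))
  expect_true(all(band0$lower <= band0$upper))
  expect_warning(bootstrap_noise_floor(es0, n_boot = 50, seed = 1),
                 "n_boot")
  # large clean response + tiny noise: average exceeds the band at the peaks
  p <- quiet_params(noise_sd_uv = 0.05)
  es <- generate_epochs(p, plan = acquisition_plan(1, 50), seed = 3)
  avg <- apply_time_corrections(alternating_average(es))
  band <- bootstrap_noise_floor(es, n_boot = 400, seed = 4)
  t <- times_ms(avg)
  for (pk in c("V", "A", "D")) {
    i <- which.min(abs(t - p$peak_latencies_ms[[pk]]))
    if (pk == "V") expect_gt(avg$waveform[i], band$upper[i])
    else expect_lt(avg$waveform[i], band$lower[i])
  }
})

test_that("band width shrinks roughly as 1/sqrt(N)", {
  p <- quiet_params(noise_sd_uv = 4)
  p$peak_amplitudes_uv[] <- 0
  p$efr_amplitude_uv <- 0
  width <- vapply(c(100, 400), function(n) {
    es <- generate_epochs(p, plan = acquisition_plan(1, n / 2), seed = 8)
    b <- bootstrap_noise_floor(es, n_boot = 300, seed = 9)
    mean(b$upper - b$lower)
  }, numeric(1))
  expect_gt(width[1] / width[2], 2 * 0.8)
  expect_lt(width[1] / width[2], 2 * 1.25)
})

test_that("peak picking recovers configured extrema with documented tie-breaks", {
  p <- quiet_params(efr_amplitude_uv = 0)
  es <- generate_epochs(p, plan = acquisition_plan(1, 2), seed = 1)
  avg <- apply_time_corrections(alternating_average(es))
  picks <- pick_peaks(avg)
  expect_equal(picks$peak, c("V", "A", "D", "E", "F", "O"))
  for (r in seq_len(nrow(picks))) {
    expect_lt(abs(picks$latency_ms[r] -
                    p$peak_latencies_ms[[picks$peak[r]]]), 0.051)
  }
  expect_false(any(picks$edge_hit))
  # monotone ramp inside a window: extremum flagged at the edge
  ramp <- as_avg(seq(0, 1, length.out = 1400))
  pr <- pick_peaks(ramp, windows = list(V = c(5, 10)))
  expect_true(pr$edge_hit)
  # exact tie resolves to the earlier latency
  w <- numeric(1400)
  w[c(700, 720)] <- -1   # two equal minima inside the D window
  pt <- pick_peaks(as_avg(w), windows = list(D = c(20, 28)))
  expect_equal(pt$latency_ms, -10 + (700 - 1) / 20)
  expect_error(pick_peaks(ramp, windows = list(V = c(10, 10))), "degenerate")
  expect_error(pick_peaks(ramp, windows = list(V = c(200, 300))), "support")
})

test_that("two-criterion detection requires bootstrap pass and repeatability", {
  p <- quiet_params(noise_sd_uv = 0.05)
  es <- generate_epochs(p, plan = acquisition_plan(2, 50), seed = 6)
  avg <- apply_time_corrections(alternating_average(es))
  band <- bootstrap_noise_floor(es, n_boot = 400, seed = 7)
  res <- assess_detection(avg, band, pick_peaks(avg))
  expect_true(all(res$detected))
  expect_true(all(res$bootstrap_pass & res$repeatable))
  # opposite-sign subaverage kills repeatability and hence detection
  avg2 <- avg
  avg2$subaverages[2, ] <- -avg2$subaverages[2, ]
  res2 <- assess_detection(avg2, band, pick_peaks(avg2))
  expect_false(any(res2$repeatable))
  expect_false(any(res2$detected))
  expect_equal(res2$detected, res2$bootstrap_pass & res2$repeatable)
})

test_that("amplitudes are peak-to-trough with the documented conventions", {
  # constructed waveform: V = +0.30 uV at 7 ms, A = -0.20 uV at 9 ms
  t <- times_ms(as_avg(numeric(1400)))
  w <- 0.30 * exp(-(t - 7)^2 / (2 * 0.25)) - 0.20 * exp(-(t - 9)^2 / (2 * 0.25))
  picks <- data.frame(
    peak = c("V", "A", "D", "E", "F", "O"),
    latency_ms = c(7, 9, 24, 33, 41, 51),
    value_uv = c(0.30, -0.20, 0, 0, 0, 0),
    edge_hit = FALSE
  )
  amp <- measure_amplitudes(as_avg(w), picks)
  expect_equal(amp$amplitude_uv[amp$peak == "V"], 0.50, tolerance = 1e-6)
  expect_true(is.na(amp$amplitude_uv[amp$peak == "A"]))
  # flat zero waveform: all amplitudes zero
  picks0 <- picks
  picks0$value_uv <- 0
  amp0 <- measure_amplitudes(as_avg(numeric(1400)), picks0)
  expect_equal(amp0$amplitude_uv[amp0$peak == "V"], 0)
  expect_true(all(amp0$amplitude_uv[amp0$peak %in% c("D", "E", "F", "O")] == 0))
  # isolated rendered peaks: measured D amplitude within 5% of configured
  p <- quiet_params(efr_amplitude_uv = 0)
  es <- generate_epochs(p, plan = acquisition_plan(1, 2), seed = 1)
  avg <- apply_time_corrections(alternating_average(es))
  res <- measure_amplitudes(avg, pick_peaks(avg))
  dmeas <- res$amplitude_uv[res$peak == "D"]
  expect_lt(abs(dmeas - abs(p$peak_amplitudes_uv[["D"]])) /
              abs(p$peak_amplitudes_uv[["D"]]), 0.05)
  # adding a constant leaves every amplitude unchanged
  avg_shift <- avg
  avg_shift$waveform <- avg$waveform + 1.23
  picks_s <- pick_peaks(avg_shift)
  expect_equal(measure_amplitudes(avg_shift, picks_s)$amplitude_uv,
               res$amplitude_uv, tolerance = 1e-9)
})

test_that("detection rate grows with response amplitude and epoch count", {
  scales <- c(0.1, 0.5, 2)
  rate_for <- function(scale, n_ep) {
    hits <- vapply(1:3, function(r) {
      p <- default_params("unaided-quiet")
      p$artifact_rate <- 0
      p$polarity_locked_amp_uv <- 0
      p$peak_amplitudes_uv <- p$peak_amplitudes_uv * scale
      p$efr_amplitude_uv <- p$efr_amplitude_uv * scale
      es <- generate_epochs(p, plan = acquisition_plan(1, n_ep / 2),
                            seed = 100 * r + scale * 10)
      avg <- apply_time_corrections(
        filter_response(alternating_average(es), low_hz = 1500))
      band <- bootstrap_noise_floor(es, n_boot = 200, seed = r,
                                    low_hz = 1500)
      mean(assess_detection(avg, band, pick_peaks(avg))$detected)
    }, numeric(1))
    mean(hits)
  }
  r_amp <- vapply(scales, rate_for, numeric(1), n_ep = 400)
  expect_true(all(diff(r_amp) >= 0))
  expect_gt(r_amp[3], r_amp[1])
  r_n <- vapply(c(100, 1600), function(n) rate_for(0.5, n), numeric(1))
  expect_gte(r_n[2], r_n[1])
})
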