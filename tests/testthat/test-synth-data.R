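test_that("default parameters encode the aiding and noise effect structure", {
  uq <- default_params("unaided-quiet")
  aq <- default_params("aided-quiet")
  un <- default_params("unaided-noise")
  # aiding: every peak earlier, every amplitude larger
  expect_true(all(aq$peak_latencies_ms < uq$peak_latencies_ms))
  expect_true(all(abs(aq$peak_amplitudes_uv) > abs(uq$peak_amplitudes_uv)))
  expect_gt(aq$efr_amplitude_uv, uq$efr_amplitude_uv)
  expect_equal(aq$efr_latency_ms, uq$efr_latency_ms)
  # background noise: peak latencies untouched, F0 encoding delayed
  expect_equal(un$peak_latencies_ms, uq$peak_latencies_ms)
  expect_equal(un$peak_amplitudes_uv, uq$peak_amplitudes_uv)
  expect_equal(un$efr_latency_ms, uq$efr_latency_ms + uq$noise_f0_delay_ms)
  # determinism and error path
  expect_identical(default_params("aided-noise", seed = 3),
                   default_params("aided-noise", seed = 3))
  expect_error(default_params("binaural-quiet"))
})

test_that("parameter invariants are enforced", {
  p <- default_params()
  bad <- p$peak_latencies_ms
  bad["A"] <- bad[["V"]] - 1
  expect_error(condition_params("unaided-quiet", bad, p$peak_amplitudes_uv,
                                0.5, 8), "ordered")
  bad2 <- p$peak_latencies_ms
  bad2["E"] <- bad2[["D"]] + 5   # below one F0 wavelength
  expect_error(condition_params("unaided-quiet", bad2, p$peak_amplitudes_uv,
                                0.5, 8), "wavelength")
  expect_error(condition_params("unaided-quiet", p$peak_latencies_ms,
                                p$peak_amplitudes_uv, 0.5, 8,
                                artifact_rate = 1.5))
  # D-E and E-F spacings of the defaults lie within one F0 wavelength
  gaps <- diff(p$peak_latencies_ms[c("D", "E", "F")])
  expect_true(all(gaps >= 1000 / 125 & gaps <= 1000 / 103))
})

test_that("rendered clean response has the configured morphology", {
  p <- quiet_params()
  # zero case
  p0 <- quiet_params(efr_amplitude_uv = 0)
  p0$peak_amplitudes_uv[] <- 0
  expect_true(all(render_clean_response(p0) == 0))
  # EFR-only: autocorrelation of the 20-50 ms segment peaks at the F0 period
  pe <- quiet_params()
  pe$peak_amplitudes_uv[] <- 0
  w <- render_clean_response(pe)
  t <- pe$efr_latency_ms  # quiet default 8 ms
  tax <- times_ms(epoch_set(matrix(w, 1), t0_ms = -10, polarity = 1L))
  seg <- w[tax >= 20 & tax <= 50]
  a <- stats::acf(seg, lag.max = round(0.0097 * 20000), plot = FALSE)$acf[-1]
  lag_ms <- seq_along(a) / 20
  in_range <- lag_ms >= 4
  best <- lag_ms[in_range][which.max(a[in_range])]
  expect_gte(best, 8.0)
  expect_lte(best, 9.7)
  # isolated deflections: minima exactly at configured D, E, F
  pd <- quiet_params(efr_amplitude_uv = 0)
  wd <- render_clean_response(pd)
  for (pk in c("D", "E", "F")) {
    L <- pd$peak_latencies_ms[[pk]]
    win <- which(tax >= L - 2 & tax <= L + 2)
    expect_lt(abs(tax[win][which.min(wd[win])] - L), 0.051)
  }
  # full defaults: minima still within half a millisecond
  wf <- render_clean_response(p)
  for (pk in c("D", "E", "F")) {
    L <- p$peak_latencies_ms[[pk]]
    win <- which(tax >= L - 2 & tax <= L + 2)
    expect_lt(abs(tax[win][which.min(wf[win])] - L), 0.5)
  }
  # latency outside the window errors
  expect_error(render_clean_response(p, window = c(-10, 30)), "window")
})

test_that("epoch generation respects the plan and the additive model", {
  p <- quiet_params()
  es <- generate_epochs(p, plan = acquisition_plan(2, 25), seed = 5)
  expect_equal(nrow(es$data), 100)  # 2 blocks x 25 x 2 polarities
  expect_equal(sum(es$polarity == 1), 50)
  expect_equal(sum(es$polarity == -1), 50)
  expect_equal(sort(unique(es$block)), c(1L, 2L))
  # noiseless epochs equal the delayed clean response exactly
  clean <- render_clean_response(p, delay_ms = p$acoustic_delay_ms)
  expect_lt(max(abs(sweep(es$data, 2, clean))), 1e-12)
  # polarity-locked arithmetic: mean(+1) - mean(-1) = 2 * locked component
  pl <- quiet_params(polarity_locked_amp_uv = 0.7)
  es2 <- generate_epochs(pl, plan = acquisition_plan(1, 4), seed = 5)
  locked <- speechABR:::polarity_locked_component(
    pl, delay_ms = pl$acoustic_delay_ms)
  diffpol <- colMeans(es2$data[es2$polarity == 1, ]) -
    colMeans(es2$data[es2$polarity == -1, ])
  expect_lt(max(abs(diffpol - 2 * locked)), 1e-12)
  # reproducibility
  expect_identical(generate_epochs(p, acquisition_plan(1, 10), seed = 9)$data,
                   generate_epochs(p, acquisition_plan(1, 10), seed = 9)$data)
})

test_that("default plan yields 10,000 epochs with artifacts above 30 uV", {
  p <- default_params("unaided-quiet")
  es <- generate_epochs(p, seed = 11)
  expect_equal(nrow(es$data), 10000L)
  expect_equal(epochs_per_condition(), 10000L)
  peak <- apply(abs(es$data), 1, max)
  n_art <- sum(peak > 30)
  # artifact_rate 0.02 -> binomial(10000, .02); allow a wide stochastic band
  expect_gt(n_art, 100)
  expect_lt(n_art, 320)
})

test_that("epoch average converges to the clean response at the 1/sqrt(N) rate", {
  p <- default_params("unaided-quiet")
  p$artifact_rate <- 0
  p$polarity_locked_amp_uv <- 0
  clean <- render_clean_response(p, delay_ms = p$acoustic_delay_ms)
  rms_err <- vapply(c(100, 1000, 10000), function(n) {
    es <- generate_epochs(p, plan = acquisition_plan(1, n / 2), seed = 21)
    sqrt(mean((colMeans(es$data) - clean)^2))
  }, numeric(1))
  expect_true(all(diff(rms_err) < 0))
  ratios <- rms_err[-3] / rms_err[-1]
  expect_true(all(ratios > sqrt(10) * 0.7 & ratios < sqrt(10) * 1.4))
})

test_that("study generation is deterministic with a complete registry", {
  st <- generate_study(3, conditions = c("unaided-quiet", "aided-quiet"),
                       seed = 2, plan = acquisition_plan(1, 5))
  expect_length(st$epoch_sets, 6)
  expect_setequal(
    names(st$ground_truth),
    as.vector(outer(sprintf("s%02d", 1:3),
                    c("unaided-quiet", "aided-quiet"), paste, sep = "/"))
  )
  # subjects differ, same seed reproduces byte-identically
  lat1 <- st$ground_truth[["s01/unaided-quiet"]]$peak_latencies_ms
  lat2 <- st$ground_truth[["s02/unaided-quiet"]]$peak_latencies_ms
  expect_false(isTRUE(all.equal(lat1, lat2)))
  st2 <- generate_study(3, conditions = c("unaided-quiet", "aided-quiet"),
                        seed = 2, plan = acquisition_plan(1, 5))
  expect_identical(st$epoch_sets[["s03/aided-quiet"]]$data,
                   st2$epoch_sets[["s03/aided-quiet"]]$data)
  # single subject, single condition
  st1 <- generate_study(1, conditions = "unaided-noise", seed = 4,
                        plan = acquisition_plan(1, 3))
  expect_length(st1$epoch_sets, 1)
  expect_length(st1$ground_truth, 1)
})

test_that("epoch CSV round trip preserves data and labels", {
  es <- generate_epochs(quiet_params(), plan = acquisition_plan(1, 3),
                        seed = 1)
  path <- file.path(withr::local_tempdir(), "epochs.csv")
  write_epoch_csv(es, path)
  es2 <- read_epoch_csv(path)
  expect_equal(es2$data, es$data, ignore_attr = TRUE)
  expect_equal(es2$polarity, es$polarity)
  expect_equal(es2$t0_ms, es$t0_ms)
  expect_equal(es2$condition, es$condition)
})
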