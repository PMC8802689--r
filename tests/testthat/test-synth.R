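# Synthetic ABR generator: generative identities, truth bookkeeping,
# determinism, artifact statistics.

test_that("epoch synthesis is deterministic given a seed", {
  p <- quiet_profile()
  e1 <- synth_epochs(click_left(), p, 20, noise_model(1, 0.2, 20), seed = 9)
  e2 <- synth_epochs(click_left(), p, 20, noise_model(1, 0.2, 20), seed = 9)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$artifact_epochs, e2$artifact_epochs)

  c1 <- synth_cohort(2, conditions = cohort_conditions(itds = 0,
                                                       frequencies_khz = NULL),
                     n_reps = 10, seed = 4)
  c2 <- synth_cohort(2, conditions = cohort_conditions(itds = 0,
                                                       frequencies_khz = NULL),
                     n_reps = 10, seed = 4)
  expect_identical(c1$animals, c2$animals)
  expect_identical(c1$truth, c2$truth)
  expect_identical(realize_trace(c1, 3)$samples, realize_trace(c2, 3)$samples)
})

test_that("amplitude clips to zero at and below the generative threshold", {
  p <- quiet_profile()   # click threshold 30 dB SPL
  expect_identical(noiseless_trace(p, click_left(30)), numeric(1172))
  expect_identical(noiseless_trace(p, click_left(10)), numeric(1172))
  expect_gt(max(abs(noiseless_trace(p, click_left(35)))), 0)
  # level gain is linear above threshold: doubling the headroom doubles it
  y1 <- noiseless_trace(p, click_left(60))
  y2 <- noiseless_trace(p, click_left(90))
  expect_samples_close(2 * y1, y2, 1e-12)
})

test_that("binaural trace decomposes into shifted ears minus the DN1 kernel", {
  p <- quiet_profile()
  for (itd in c(0, 1)) {
    tri <- noiseless_triplet(p, itd)
    resid <- tri$binaural$samples - tri$left$samples - tri$right$samples
    tr <- true_dn1(p, click_both(itd = itd))
    t <- abr_time_ms()
    dn1 <- -tr$amplitude_av * exp(-((t - tr$latency_ms) /
                                      p$dn1$width_ms)^2 / 2)
    expect_samples_close(resid, dn1, 1e-12)
  }
  # with the DN1 amplitude at zero the superposition is exactly linear
  p0 <- quiet_profile(dn1 = dn1_params(base_amplitude_av = 0))
  tri <- noiseless_triplet(p0, 0)
  expect_samples_close(
    tri$binaural$samples, tri$left$samples + tri$right$samples, 1e-12)
})

test_that("wave IV multiplier scales the generated deflection and its truth", {
  eff <- group_effects(wave4_amp_multiplier = c("female:Fmr1" = 0.7),
                       animal_sd_av = 0)
  p_mut <- animal_profile("m", "female", "Fmr1", effects = eff)
  p_wt <- animal_profile("w", "female", "B6", effects = eff)
  tw_mut <- true_waves(p_mut, click_left())
  tw_wt <- true_waves(p_wt, click_left())
  expect_equal(tw_mut$amplitude_av[4], 0.7 * tw_wt$amplitude_av[4],
               tolerance = 1e-9)
  expect_equal(tw_mut$amplitude_av[1:3], tw_wt$amplitude_av[1:3],
               tolerance = 1e-12)
  # the synthesized waveform extremum matches the truth record
  y <- noiseless_trace(p_mut, click_left())
  t <- abr_time_ms()
  ip <- which.min(abs(t - tw_mut$peak_latency_ms[4]))
  expect_equal(max(y[(ip - 3):(ip + 3)]), tw_mut$peak_value_av[4],
               tolerance = 1e-9)
})

test_that("waveform extrema match truth records at noise 0", {
  p <- quiet_profile()
  for (spec in list(click_left(), click_left(60),
                    stimulus_spec("tone", "left", 70, 8))) {
    y <- noiseless_trace(p, spec)
    tw <- true_waves(p, spec)
    t <- abr_time_ms()
    for (i in 1:4) {
      ip <- which.min(abs(t - tw$peak_latency_ms[i]))
      expect_lt(abs(max(y[(ip - 3):(ip + 3)]) - tw$peak_value_av[i]), 1e-9)
      # troughs sit closer to the following wave, whose Gaussian tail
      # contributes up to ~1e-6 aV at the default spacing
      it <- which.min(abs(t - tw$trough_latency_ms[i]))
      expect_lt(abs(min(y[(it - 3):(it + 3)]) - tw$trough_value_av[i]), 1e-6)
    }
  }
})

test_that("DN1 truth is monotone in |ITD| and shifts only at 0 ITD", {
  p <- quiet_profile(id = "b6m", sex = "male")
  itds <- itd_grid_ms()
  tr <- lapply(itds, function(itd) true_dn1(p, click_both(itd = itd)))
  amp <- vapply(tr, `[[`, numeric(1), "amplitude_av")
  lat <- vapply(tr, `[[`, numeric(1), "latency_ms")
  pos <- itds >= 0
  expect_true(all(diff(amp[pos]) < 0))   # strictly decreasing in |ITD|
  expect_true(all(diff(lat[pos]) > 0))   # strictly increasing in |ITD|
  expect_equal(amp[itds < 0], rev(amp[itds > 0]), tolerance = 1e-12)

  eff <- group_effects(dn1_latency_shift_ms = c("male:Fmr1" = 0.2),
                       animal_sd_av = 0)
  p_mut <- animal_profile("fx", "male", "Fmr1", effects = eff)
  p_wt <- animal_profile("wt", "male", "B6", effects = eff)
  d0 <- true_dn1(p_mut, click_both(itd = 0))$latency_ms -
    true_dn1(p_wt, click_both(itd = 0))$latency_ms
  expect_equal(d0, 0.2, tolerance = 1e-12)
  d1 <- true_dn1(p_mut, click_both(itd = 0.5))$latency_ms -
    true_dn1(p_wt, click_both(itd = 0.5))$latency_ms
  expect_equal(d1, 0, tolerance = 1e-12)
})

test_that("artifact frequency matches the generative rate", {
  set.seed(31)
  p <- quiet_profile()
  nm <- noise_model(1, artifact_rate = 0.1, artifact_amplitude_av = 50)
  e <- synth_epochs(click_left(), p, 1500, nm)
  phat <- length(e$artifact_epochs) / 1500
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / 1500))
})

test_that("stimulus validation rejects off-grid ITDs and bad levels", {
  expect_error(stimulus_spec("click", "both", 90, itd_ms = 0.3), "grid")
  expect_error(stimulus_spec("click", "left", -5), "level")
  expect_error(stimulus_spec("tone", "left", 70, frequency_khz = 5), "kHz")
  expect_error(stimulus_spec("click", "left", 70, frequency_khz = 8),
               "broadband")
  expect_error(synth_binaural_epoch(click_left(), quiet_profile()), "both")
})
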