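# Wave I-IV detection and quantification.

test_that("noiseless traces are quantified at generator truth", {
  p <- quiet_profile()
  pk <- detect_peaks(raw_trace(p, click_left()))
  tw <- true_waves(p, click_left())
  expect_true(all(!pk$missing))
  expect_true(all(abs(pk$peak_latency_ms - tw$peak_latency_ms) <=
                    MS_PER_SAMPLE + 1e-12))
  expect_true(all(abs(pk$amplitude_av / tw$amplitude_av - 1) < 0.01))
  expect_true(all(pk$trough_latency_ms > pk$peak_latency_ms))
  expect_true(all(pk$amplitude_av >= 0))
  expect_true(all(diff(pk$peak_latency_ms) > 0))
})

test_that("a lone deflection yields one wave and three explicit absences", {
  t <- abr_time_ms()
  bump <- exp(-((t - 1.3) / 0.1)^2 / 2)
  pk <- detect_peaks(abr_trace(bump), min_prominence = 0.3)
  expect_identical(pk$missing, c(FALSE, TRUE, TRUE, TRUE))
  expect_true(all(is.na(pk$amplitude_av[2:4])))
  flat <- detect_peaks(abr_trace(numeric(1172)), min_prominence = 0.1)
  expect_true(all(flat$missing))
})

test_that("false wave detection on pure noise stays rare at 6 sigma", {
  set.seed(1)
  n_false <- 0
  for (r in 1:200) {
    pk <- detect_peaks(abr_trace(rnorm(1172)), min_prominence = 6)
    n_false <- n_false + sum(!pk$missing)
  }
  expect_lte(n_false / (200 * 4), 0.05)
})

test_that("manual overrides edit, clear and recompute by the trough rule", {
  p <- quiet_profile()
  tr <- raw_trace(p, click_left())
  pk <- detect_peaks(tr)

  cleared <- apply_manual_override(pk, clear = "III")
  expect_true(cleared$missing[3])
  expect_identical(cleared$source[3], "manual")
  expect_identical(sum(!cleared$missing), 3L)

  # re-setting a wave at its detected position flips only its source
  same <- apply_manual_override(pk, set = c(I = pk$peak_latency_ms[1]))
  expect_identical(same$source[1], "manual")
  expect_equal(same$amplitude_av[1], pk$amplitude_av[1], tolerance = 1e-12)
  expect_equal(same$peak_latency_ms[1], pk$peak_latency_ms[1])

  # moving wave IV two samples later changes the amplitude exactly by the
  # trace-value difference between the two peak samples (trough unchanged)
  t <- trace_time_ms(tr)
  i_old <- which.min(abs(t - pk$peak_latency_ms[4]))
  i_new <- i_old + 2L
  moved <- apply_manual_override(pk, set = c(IV = t[i_new]))
  expect_equal(moved$amplitude_av[4] - pk$amplitude_av[4],
               tr$samples[i_new] - tr$samples[i_old], tolerance = 1e-12)
  expect_equal(moved$trough_latency_ms[4], pk$trough_latency_ms[4])

  # ordering violations are rejected with an explanation
  expect_error(apply_manual_override(pk, set = c(IV = 2.0)),
               "strictly\\s+increasing")
  expect_error(apply_manual_override(pk, set = c(I = 20)), "outside")
})

test_that("monaural summary averages ears and flags single-ear fallback", {
  p <- quiet_profile()
  tr <- raw_trace(p, click_left())
  tr2 <- tr; tr2$samples <- 2 * tr$samples   # right 'ear' at twice the gain
  left <- detect_peaks(tr)
  right <- detect_peaks(tr2)
  s <- monaural_summary(left, right)
  expect_equal(s$amplitude_av, 1.5 * left$amplitude_av, tolerance = 1e-9)
  expect_equal(s$latency_ms, left$peak_latency_ms, tolerance = 1e-9)
  expect_identical(s$n_ears, rep(2L, 4))

  s_id <- monaural_summary(left, left)
  expect_equal(s_id$amplitude_av, left$amplitude_av)

  right_m <- apply_manual_override(right, clear = "II")
  s2 <- monaural_summary(left, right_m)
  expect_true(s2$flagged[2])
  expect_equal(s2$amplitude_av[2], left$amplitude_av[2])
  both_m <- monaural_summary(apply_manual_override(left, clear = "II"),
                             right_m)
  expect_true(is.na(both_m$amplitude_av[2]))
})

test_that("detection is translation-equivariant and scale-covariant", {
  p <- quiet_profile()
  tr <- raw_trace(p, click_left())
  pk <- detect_peaks(tr)
  k <- 25L
  shifted <- abr_trace(c(numeric(k), tr$samples[1:(1172 - k)]))
  wins <- wave_windows()
  wins$lo_ms <- wins$lo_ms + k * MS_PER_SAMPLE
  wins$hi_ms <- wins$hi_ms + k * MS_PER_SAMPLE
  pk_s <- detect_peaks(shifted, windows = wins)
  expect_equal(pk_s$peak_latency_ms - pk$peak_latency_ms,
               rep(k * MS_PER_SAMPLE, 4), tolerance = 1e-12)

  scaled <- abr_trace(3.7 * tr$samples)
  pk_c <- detect_peaks(scaled)
  expect_equal(pk_c$amplitude_av, 3.7 * pk$amplitude_av, tolerance = 1e-12)
  expect_equal(pk_c$peak_latency_ms, pk$peak_latency_ms)
})

test_that("assignment stays accurate on noisy averaged traces", {
  # 100 averaged traces at the 500-sweep operating point
  set.seed(2)
  p <- quiet_profile()
  nm <- noise_model(1, 0, 20)
  ref <- detect_peaks(preprocess_trace(raw_trace(p, click_left())))
  n_ok <- 0
  for (r in 1:100) {
    tr <- preprocess_trace(synth_averaged_trace(click_left(), p, nm,
                                                n_reps = 500))
    pk <- detect_peaks(tr)
    ok <- !pk$missing &
      abs(pk$peak_latency_ms - ref$peak_latency_ms) <= MS_PER_SAMPLE + 1e-12
    n_ok <- n_ok + sum(ok)
  }
  expect_gte(n_ok / 400, 0.99)
})
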