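# Hearing-threshold estimation and audiogram assembly.

test_that("response detection applies a strict criterion boundary", {
  expect_false(detect_response(abr_trace(numeric(1172)), noise_floor = 0.1))
  # trace whose window RMS equals exactly criterion * floor: not detected
  tr <- abr_trace(rep(1, 1172))
  expect_false(detect_response(tr, noise_floor = 0.5, criterion_multiple = 2))
  expect_true(detect_response(tr, noise_floor = 0.49, criterion_multiple = 2))
  # noiseless suprathreshold trace against a small floor
  p <- quiet_profile()
  expect_true(detect_response(raw_trace(p, click_left()), noise_floor = 0.01))
  expect_error(detect_response(tr, 0.1, window_ms = c(6, 6)), "window")
  expect_error(detect_response(tr, 0.1, method = "template"), "template")
})

test_that("threshold search reports the lowest persistently detected level", {
  p <- quiet_profile()   # 8 kHz generative threshold 35 dB SPL
  levels <- seq(90, 20, by = -5)
  mk_series <- function(profile, f) {
    lapply(levels, function(lv) {
      raw_trace(profile, stimulus_spec("tone", "left", lv, f))
    })
  }
  th <- estimate_threshold(mk_series(p, 8), levels, method = "template")
  # response is exactly zero at the 35 dB generative threshold, so the
  # lowest detectable level is one step above it
  expect_identical(th$threshold_db, 40)
  expect_identical(estimate_threshold(mk_series(p, 8), levels,
                                      method = "rms")$threshold_db, 40)

  # detection at every level: the lowest tested level is returned
  low <- animal_profile("lo", "female", "B6", effects = null_effects(),
                        audiogram = c(`1` = 65, `2` = 55, `4` = 45, `8` = 10,
                                      `16` = 30, `24` = 30, `32` = 35,
                                      `46` = 45))
  th_all <- estimate_threshold(mk_series(low, 8), levels, noise_floor = 1e-6,
                               method = "template",
                               template = mk_series(low, 8)[[1]])
  expect_identical(th_all$threshold_db, 20)

  # no detection at the top level: no-response
  deaf <- animal_profile("hi", "female", "B6", effects = null_effects(),
                         audiogram = c(`1` = 65, `2` = 55, `4` = 45,
                                       `8` = 95, `16` = 30, `24` = 30,
                                       `32` = 35, `46` = 45))
  expect_true(is.na(estimate_threshold(mk_series(deaf, 8), levels,
                                       method = "template")$threshold_db))

  expect_error(estimate_threshold(mk_series(p, 8), rev(levels)),
               "descending")
  expect_error(estimate_threshold(mk_series(p, 8)[c(1, 4, 7, 10)],
                                  levels[c(1, 4, 7, 10)]),
               "\\[5, 10\\]")
})

test_that("raising the detection criterion never lowers a threshold", {
  set.seed(21)
  p <- quiet_profile()
  nm <- noise_model(1, 0, 20)
  levels <- seq(90, 20, by = -5)
  for (r in 1:10) {
    traces <- lapply(levels, function(lv) {
      preprocess_trace(synth_averaged_trace(
        stimulus_spec("tone", "left", lv, 16), p, nm, n_reps = 200))
    })
    th <- vapply(c(1.5, 2, 3, 5), function(k) {
      x <- estimate_threshold(traces, levels, criterion_multiple = k,
                              method = "template")$threshold_db
      if (is.na(x)) Inf else x
    }, numeric(1))
    expect_true(all(diff(th) >= 0))
  }
})

test_that("audiograms assemble, deduplicate and mark no-response", {
  p <- quiet_profile()
  levels <- seq(90, 20, by = -5)
  series <- lapply(tone_frequencies_khz(), function(f) {
    list(traces = lapply(levels, function(lv) {
      raw_trace(p, stimulus_spec("tone", "left", lv, f))
    }), levels = levels)
  })
  names(series) <- as.character(tone_frequencies_khz())
  ag <- build_audiogram(series, method = "template")
  expect_identical(nrow(ag), 8L)
  # noiseless estimates sit exactly one 5 dB step above generative truth
  expect_equal(ag$threshold_db, unname(default_audiogram()) + 5)
  ag2 <- build_audiogram(series, method = "template")
  expect_identical(as.data.frame(ag), as.data.frame(ag2))  # deterministic

  expect_error(build_audiogram(series[c(1, 1)]), "duplicate")
  expect_error(build_audiogram(stats::setNames(series[1], "3")), "frequencies")

  flat <- abr_trace(numeric(1172))
  dead <- list(`8` = list(traces = rep(list(flat), 4),
                          levels = c(90, 80, 70, 60)))
  ag_no <- build_audiogram(dead, noise_floor = 1)
  expect_true(all(ag_no$no_response))
})

test_that("a high-frequency threshold shift is recovered at 32 and 46 kHz", {
  eff <- group_effects(highfreq_threshold_shift_db = c("male:Fmr1" = 15),
                       animal_sd_av = 0)
  audiograms <- lapply(c("Fmr1", "B6"), function(g) {
    p <- animal_profile(g, "male", g, effects = eff)
    levels <- seq(90, 20, by = -5)
    series <- lapply(tone_frequencies_khz(), function(f) {
      list(traces = lapply(levels, function(lv) {
        raw_trace(p, stimulus_spec("tone", "left", lv, f))
      }), levels = levels)
    })
    names(series) <- as.character(tone_frequencies_khz())
    build_audiogram(series, method = "template")
  })
  delta <- audiograms[[1]]$threshold_db - audiograms[[2]]$threshold_db
  expect_equal(delta, c(0, 0, 0, 0, 0, 0, 15, 15))
})
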