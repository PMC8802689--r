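# Shared fixtures: everything is generated in code at test time.

MS_PER_SAMPLE <- 1000 / abr_fs()

# A deterministic animal with no per-animal variability.
quiet_profile <- function(id = "a1", sex = "female", genotype = "B6", ...) {
  animal_profile(id, sex = sex, genotype = genotype,
                 effects = null_effects(), ...)
}

click_left <- function(level = 90) stimulus_spec("click", "left", level)
click_both <- function(level = 90, itd = 0) {
  stimulus_spec("click", "both", level, itd_ms = itd)
}

# Raw (unprocessed) noiseless trace for a condition.
raw_trace <- function(profile, spec) {
  abr_trace(noiseless_trace(profile, spec), spec = spec,
            animal = profile$id)
}

# Noiseless per-ITD triplet (left/right components with matching stimulus
# delays plus the binaural trace), optionally preprocessed.
noiseless_triplet <- function(profile, itd, level = 90, process = FALSE,
                              settings = preprocess_settings(filter = FALSE)) {
  mk <- function(ear) {
    tr <- raw_trace(profile, stimulus_spec("click", ear, level, itd_ms = itd))
    if (process) preprocess_trace(tr, settings) else tr
  }
  list(left = mk("left"), right = mk("right"), binaural = mk("both"))
}

expect_samples_close <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
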