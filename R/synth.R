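# Synthetic ABR generator: stimulus descriptors, wave kernels, group effects,
# noise model, per-epoch synthesis and generative truth bookkeeping.

## ---- acquisition constants -------------------------------------------------

#' Acquisition constants
#'
#' The recording convention emulated throughout the package: a 12 ms window
#' sampled at 97656.25 Hz starting at stimulus onset.  The sample count is
#' `ceiling(0.012 * fs)` = 1172, with the time axis `t = n / fs`,
#' `n = 0 ... 1171`.
#'
#' @format `abr_fs()` returns the sampling rate in Hz, `abr_n_samples()` the
#'   number of samples in one epoch, and `abr_time_ms()` the time axis in ms.
#' @name abr-constants
NULL

ABR_FS <- 97656.25
ABR_WINDOW_MS <- 12
ABR_N_SAMPLES <- 1172L

#' @rdname abr-constants
#' @export
abr_fs <- function() ABR_FS

#' @rdname abr-constants
#' @export
abr_n_samples <- function() ABR_N_SAMPLES

#' @rdname abr-constants
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @export
abr_time_ms <- function(n = ABR_N_SAMPLES, fs = ABR_FS) {
  (seq_len(n) - 1) / fs * 1000
}

#' Interaural time difference grid (ms)
#'
#' ITDs used for binaural series: -2 to +2 ms in 0.5 ms steps.  Positive
#' values mean the left ear leads.
#' @export
itd_grid_ms <- function() seq(-2, 2, by = 0.5)

#' Audiogram tone frequencies (kHz)
#' @export
tone_frequencies_khz <- function() c(1, 2, 4, 8, 16, 24, 32, 46)

## ---- stimulus specification ------------------------------------------------

#' Stimulus specification
#'
#' Describes one stimulus condition.  Clicks carry no frequency; tones must
#' use one of the eight audiogram frequencies.  `itd_ms` must lie on the
#' +/-2 ms grid in 0.5 ms steps and is normally present only for binaural
#' (`ear = "both"`) stimuli; a monaural spec may also carry an ITD, in which
#' case it denotes the monaural *component* of that binaural condition,
#' i.e. the ear's stimulus is delayed exactly as in the binaural
#' presentation (needed so summed and binaural traces align when forming the
#' binaural interaction component).
#'
#' @param modality `"click"` or `"tone"`.
#' @param ear `"left"`, `"right"` or `"both"`.
#' @param level stimulus level in dB SPL (>= 0).
#' @param frequency_khz tone frequency in kHz; `NULL` for clicks.
#' @param itd_ms interaural time difference in ms (positive = left leads).
#' @param isi_mean_ms,isi_sd_ms interstimulus-interval metadata (ms); epochs
#'   are generated as already-segmented windows, so these are descriptive
#'   only.
#' @return an object of class `abr_stimulus`.
#' @export
stimulus_spec <- function(modality = c("click", "tone"),
                          ear = c("left", "right", "both"),
                          level = 90,
                          frequency_khz = NULL,
                          itd_ms = NULL,
                          isi_mean_ms = 30,
                          isi_sd_ms = 5) {
  modality <- match.arg(modality)
  ear <- match.arg(ear)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) || level < 0) {
    stop("`level` must be a single non-negative dB SPL value", call. = FALSE)
  }
  if (modality == "tone") {
    if (is.null(frequency_khz) ||
        !any(abs(frequency_khz - tone_frequencies_khz()) < 1e-9)) {
      stop("tone `frequency_khz` must be one of ",
           paste(tone_frequencies_khz(), collapse = ", "), " kHz",
           call. = FALSE)
    }
  } else if (!is.null(frequency_khz)) {
    stop("clicks are broadband: `frequency_khz` must be NULL", call. = FALSE)
  }
  if (ear == "both" && is.null(itd_ms)) itd_ms <- 0
  if (!is.null(itd_ms)) {
    if (!any(abs(itd_ms - itd_grid_ms()) < 1e-9)) {
      stop("`itd_ms` must lie on the ±2 ms grid in 0.5 ms steps",
           call. = FALSE)
    }
    itd_ms <- itd_grid_ms()[which.min(abs(itd_ms - itd_grid_ms()))]
  }
  structure(
    list(modality = modality, ear = ear, level = level,
         frequency_khz = frequency_khz, itd_ms = itd_ms,
         isi_mean_ms = isi_mean_ms, isi_sd_ms = isi_sd_ms),
    class = "abr_stimulus"
  )
}

#' @export
print.abr_stimulus <- function(x, ...) {
  cat(sprintf("<abr_stimulus> %s, ear=%s, %g dB SPL%s%s\n",
              x$modality, x$ear, x$level,
              if (is.null(x$frequency_khz)) "" else
                sprintf(", %g kHz", x$frequency_khz),
              if (is.null(x$itd_ms)) "" else
                sprintf(", ITD %+g ms", x$itd_ms)))
  invisible(x)
}

## ---- generator parameter objects -------------------------------------------

#' Wave kernel parameters
#'
#' Morphology of the four ABR waves.  Each wave is a Gaussian-windowed
#' biphasic deflection (positive lobe followed by a trough 2.5 widths later)
#' whose peak-to-trough extent at the reference gain equals
#' `base_amplitude_av`.  Latencies must be strictly increasing and the whole
#' complex must fit in the 12 ms window.
#'
#' @param base_latency_ms peak latencies (ms) for waves I-IV.
#' @param base_amplitude_av peak-to-trough amplitudes (arbitrary voltage
#'   units, aV) at the 90 dB SPL click reference.
#' @param width_ms Gaussian widths (ms).
#' @param latency_jitter_sd_ms per-animal latency jitter SD (ms), applied
#'   once per animal when a profile is realized.
#' @return object of class `abr_kernels`.
#' @export
wave_kernels <- function(base_latency_ms = c(1.3, 2.2, 3.1, 4.3),
                         base_amplitude_av = c(1.2, 0.9, 0.7, 1.0),
                         width_ms = c(0.10, 0.10, 0.12, 0.13),
                         latency_jitter_sd_ms = 0) {
  stopifnot(length(base_latency_ms) == 4L,
            length(base_amplitude_av) == 4L,
            length(width_ms) == 4L)
  if (any(diff(base_latency_ms) <= 0)) {
    stop("wave latencies must be strictly increasing", call. = FALSE)
  }
  if (any(width_ms <= 0)) stop("wave widths must be positive", call. = FALSE)
  if (any(base_amplitude_av < 0)) {
    stop("wave amplitudes must be non-negative", call. = FALSE)
  }
  if (max(base_latency_ms + 4 * width_ms) >= ABR_WINDOW_MS) {
    stop("wave complex does not fit in the 12 ms window", call. = FALSE)
  }
  structure(
    list(base_latency_ms = base_latency_ms,
         base_amplitude_av = base_amplitude_av,
         width_ms = width_ms,
         latency_jitter_sd_ms = latency_jitter_sd_ms),
    class = "abr_kernels"
  )
}

#' DN1 (binaural interaction component) generator parameters
#'
#' The binaural trace is the sum of the two (delay-shifted) monaural
#' responses minus a negative Gaussian DN1 deflection.  Its magnitude decays
#' exponentially with |ITD| (`amp * exp(-|itd|/tau)`) and its latency grows
#' linearly (`latency + slope * |itd|`), matching the qualitative behaviour
#' of the rodent BIC.
#'
#' @param base_latency_ms DN1 trough latency at 0 ITD (ms); sits just after
#'   the wave IV peak.
#' @param base_amplitude_av DN1 magnitude at 0 ITD and reference gain (aV).
#' @param width_ms Gaussian width (ms).
#' @param itd_decay_tau_ms exponential amplitude decay constant (ms).
#' @param itd_latency_slope latency growth per ms of |ITD| (ms/ms).
#' @return object of class `abr_dn1_params`.
#' @export
dn1_params <- function(base_latency_ms = 4.5,
                       base_amplitude_av = 0.6,
                       width_ms = 0.15,
                       itd_decay_tau_ms = 2,
                       itd_latency_slope = 0.1) {
  stopifnot(base_latency_ms > 0, base_amplitude_av >= 0, width_ms > 0,
            itd_decay_tau_ms > 0, itd_latency_slope >= 0)
  structure(
    list(base_latency_ms = base_latency_ms,
         base_amplitude_av = base_amplitude_av,
         width_ms = width_ms,
         itd_decay_tau_ms = itd_decay_tau_ms,
         itd_latency_slope = itd_latency_slope),
    class = "abr_dn1_params"
  )
}

#' Group-level effects
#'
#' Sex-by-genotype effects injected by the generator.  Each effect is a
#' named numeric vector keyed `"sex:genotype"` (e.g. `"female:Fmr1"`);
#' unnamed groups take the null value (multiplier 1, shift 0).
#'
#' @param wave4_amp_multiplier multiplicative factor on the wave IV
#'   amplitude (e.g. `c("female:Fmr1" = 0.7)`); must be positive.
#' @param dn1_latency_shift_ms additive DN1 latency shift applied at 0 ITD
#'   only (ms).
#' @param highfreq_threshold_shift_db additive hearing-threshold shift at 32
#'   and 46 kHz (dB).
#' @param animal_sd_av per-animal random intercept SD on wave amplitudes
#'   (aV).
#' @return object of class `abr_effects`.
#' @export
group_effects <- function(wave4_amp_multiplier = NULL,
                          dn1_latency_shift_ms = NULL,
                          highfreq_threshold_shift_db = NULL,
                          animal_sd_av = 0.1) {
  check_named <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")) {
      stop("`", what, "` must be a named numeric vector keyed 'sex:genotype'",
           call. = FALSE)
    }
    if (!all(is.finite(x))) stop("`", what, "` must be finite", call. = FALSE)
    x
  }
  wave4_amp_multiplier <- check_named(wave4_amp_multiplier,
                                      "wave4_amp_multiplier")
  if (!is.null(wave4_amp_multiplier) && any(wave4_amp_multiplier <= 0)) {
    stop("wave IV multipliers must be positive", call. = FALSE)
  }
  dn1_latency_shift_ms <- check_named(dn1_latency_shift_ms,
                                      "dn1_latency_shift_ms")
  highfreq_threshold_shift_db <- check_named(highfreq_threshold_shift_db,
                                             "highfreq_threshold_shift_db")
  stopifnot(is.numeric(animal_sd_av), animal_sd_av >= 0)
  structure(
    list(wave4_amp_multiplier = wave4_amp_multiplier,
         dn1_latency_shift_ms = dn1_latency_shift_ms,
         highfreq_threshold_shift_db = highfreq_threshold_shift_db,
         animal_sd_av = animal_sd_av),
    class = "abr_effects"
  )
}

#' Null group effects (no group differences, no animal variability)
#' @param animal_sd_av per-animal random intercept SD (aV), default 0.
#' @export
null_effects <- function(animal_sd_av = 0) {
  group_effects(animal_sd_av = animal_sd_av)
}

lookup_effect <- function(x, sex, genotype, default) {
  if (is.null(x)) return(default)
  key <- paste(sex, genotype, sep = ":")
  if (key %in% names(x)) unname(x[[key]]) else default
}

#' Epoch noise model
#'
#' Background activity is white Gaussian noise per epoch; with probability
#' `artifact_rate` an epoch additionally carries a large, slow, heartbeat-like
#' transient of fixed magnitude `artifact_amplitude_av` at a random position
#' (kept fully inside the window so that artifact epochs always exceed a
#' rejection threshold set between the background and artifact scales).
#'
#' @param background_sd_av white-noise SD per epoch (aV).
#' @param artifact_rate probability per epoch of an artifact, in `[0, 1]`.
#' @param artifact_amplitude_av artifact scale (aV); must exceed
#'   `background_sd_av` so rejection is well defined.
#' @return object of class `abr_noise`.
#' @export
noise_model <- function(background_sd_av = 1.0,
                        artifact_rate = 0.05,
                        artifact_amplitude_av = 20) {
  stopifnot(background_sd_av >= 0,
            artifact_rate >= 0, artifact_rate <= 1,
            artifact_amplitude_av >= 0)
  if (artifact_rate > 0 && artifact_amplitude_av <= background_sd_av) {
    stop("`artifact_amplitude_av` must exceed `background_sd_av`",
         call. = FALSE)
  }
  structure(
    list(background_sd_av = background_sd_av,
         artifact_rate = artifact_rate,
         artifact_amplitude_av = artifact_amplitude_av),
    class = "abr_noise"
  )
}

#' Noise-free noise model
#' @export
no_noise <- function() noise_model(background_sd_av = 0, artifact_rate = 0)

## ---- kernels ---------------------------------------------------------------

# Peak-to-trough extent of the unit biphasic shape
# f(u) = exp(-u^2/2) - exp(-(u-2.5)^2/2); constant across widths because the
# trough separation is fixed at 2.5 widths.
.kernel_norm <- local({
  u <- seq(-6, 8.5, by = 5e-4)
  s <- exp(-u^2 / 2) - exp(-(u - 2.5)^2 / 2)
  max(s) - min(s)
})

# Biphasic wave kernel: positive lobe at `latency_ms`, trough ~2.5 widths
# later, scaled so peak-to-trough equals `amplitude_av`.
biphasic_kernel <- function(t_ms, latency_ms, width_ms, amplitude_av) {
  x <- (t_ms - latency_ms) / width_ms
  (amplitude_av / .kernel_norm) * (exp(-x^2 / 2) - exp(-(x - 2.5)^2 / 2))
}

# Negative Gaussian DN1 kernel with unit-magnitude scaling.
dn1_kernel <- function(t_ms, latency_ms, width_ms, amplitude_av) {
  -amplitude_av * exp(-((t_ms - latency_ms) / width_ms)^2 / 2)
}

# Linear suprathreshold amplitude growth; zero at and below threshold.
level_gain <- function(level, threshold, slope_per_db = 1 / 60) {
  pmax(0, level - threshold) * slope_per_db
}

# Stimulus delay for one ear under an ITD (positive ITD = left leads, i.e.
# the left stimulus arrives itd/2 early and the right itd/2 late).
ear_delay_ms <- function(ear, itd_ms) {
  if (is.null(itd_ms)) return(0)
  switch(ear, left = -itd_ms / 2, right = +itd_ms / 2,
         stop("ear_delay_ms() is per-ear"))
}

## ---- animal profiles -------------------------------------------------------

#' Baseline audiogram (dB SPL by frequency)
#'
#' Generative hearing thresholds per tone frequency for an unaffected
#' animal, shaped like the mouse audiogram (best hearing 8-46 kHz).
#' @export
default_audiogram <- function() {
  c(`1` = 65, `2` = 55, `4` = 45, `8` = 35,
    `16` = 30, `24` = 30, `32` = 35, `46` = 45)
}

#' Realize one synthetic animal
#'
#' Draws the per-animal generative parameters (latency jitter, amplitude
#' intercept, group-shifted thresholds and DN1 latency) from the population
#' objects.  Uses the current RNG state; seed externally for reproducibility.
#'
#' @param id animal identifier.
#' @param sex `"female"` or `"male"`.
#' @param genotype `"B6"`, `"Fmr1"` or `"Fmr1 het"`.
#' @param litter `"mixed"` or `"single"` genotype mating.
#' @param kernels [wave_kernels()] object.
#' @param effects [group_effects()] object.
#' @param dn1 [dn1_params()] object.
#' @param audiogram named baseline thresholds, see [default_audiogram()].
#' @param click_threshold_db generative click threshold (dB SPL).
#' @param amp_slope_per_db linear amplitude growth per dB above threshold;
#'   the default 1/60 makes the gain exactly 1 at a 90 dB click.
#' @return object of class `abr_profile` holding the realized generative
#'   truth for this animal.
#' @export
animal_profile <- function(id, sex = c("female", "male"),
                           genotype = c("B6", "Fmr1", "Fmr1 het"),
                           litter = c("mixed", "single"),
                           kernels = wave_kernels(),
                           effects = null_effects(),
                           dn1 = dn1_params(),
                           audiogram = default_audiogram(),
                           click_threshold_db = 30,
                           amp_slope_per_db = 1 / 60) {
  sex <- match.arg(sex)
  genotype <- match.arg(genotype)
  litter <- match.arg(litter)

  jit <- if (kernels$latency_jitter_sd_ms > 0) {
    stats::rnorm(4, 0, kernels$latency_jitter_sd_ms)
  } else rep(0, 4)
  latencies <- kernels$base_latency_ms + jit
  if (any(diff(latencies) <= 0)) latencies <- sort(latencies)

  offset <- if (effects$animal_sd_av > 0) {
    stats::rnorm(1, 0, effects$animal_sd_av)
  } else 0
  amps <- kernels$base_amplitude_av
  amps[4] <- amps[4] * lookup_effect(effects$wave4_amp_multiplier,
                                     sex, genotype, 1)
  amps <- pmax(0.05, amps + offset)

  thr <- audiogram
  hf <- lookup_effect(effects$highfreq_threshold_shift_db, sex, genotype, 0)
  thr[c("32", "46")] <- thr[c("32", "46")] + hf

  structure(
    list(id = id, sex = sex, genotype = genotype, litter = litter,
         wave_latency_ms = latencies,
         wave_amplitude_av = amps,
         wave_width_ms = kernels$width_ms,
         amp_offset_av = offset,
         thresholds_db = thr,
         click_threshold_db = click_threshold_db,
         amp_slope_per_db = amp_slope_per_db,
         dn1 = dn1,
         dn1_shift0_ms = lookup_effect(effects$dn1_latency_shift_ms,
                                       sex, genotype, 0)),
    class = "abr_profile"
  )
}

#' @export
print.abr_profile <- function(x, ...) {
  cat(sprintf("<abr_profile> %s (%s %s, %s litter)\n",
              x$id, x$sex, x$genotype, x$litter))
  cat(sprintf("  wave latencies (ms): %s\n",
              paste(sprintf("%.3f", x$wave_latency_ms), collapse = ", ")))
  cat(sprintf("  wave amplitudes (aV): %s\n",
              paste(sprintf("%.3f", x$wave_amplitude_av), collapse = ", ")))
  invisible(x)
}

profile_threshold <- function(profile, spec) {
  if (spec$modality == "click") {
    profile$click_threshold_db
  } else {
    unname(profile$thresholds_db[as.character(spec$frequency_khz)])
  }
}

# DN1 generative latency/magnitude for one profile and ITD.
dn1_truth_at <- function(profile, itd_ms, gain) {
  d <- profile$dn1
  shift0 <- if (abs(itd_ms) < 1e-12) profile$dn1_shift0_ms else 0
  list(
    latency_ms = d$base_latency_ms + d$itd_latency_slope * abs(itd_ms) + shift0,
    amplitude_av = d$base_amplitude_av * gain * exp(-abs(itd_ms) / d$itd_decay_tau_ms)
  )
}

## ---- noiseless synthesis and truth -----------------------------------------

#' Noise-free evoked trace for a stimulus condition
#'
#' Evaluates the generative model on the sample grid: the sum of the four
#' biphasic wave kernels (per active ear, with the ear's ITD stimulus delay
#' applied to the kernel latencies), minus the DN1 kernel for binaural
#' stimuli.  Amplitudes scale linearly with level above the condition's
#' generative threshold and are exactly zero at and below it.
#'
#' @param profile [animal_profile()] object.
#' @param spec [stimulus_spec()] object.
#' @param fs sampling rate (Hz).
#' @param n_samples samples per epoch.
#' @return numeric vector of length `n_samples` (aV).
#' @export
noiseless_trace <- function(profile, spec, fs = ABR_FS,
                            n_samples = ABR_N_SAMPLES) {
  stopifnot(inherits(profile, "abr_profile"), inherits(spec, "abr_stimulus"))
  t <- abr_time_ms(n_samples, fs)
  gain <- level_gain(spec$level, profile_threshold(profile, spec),
                     profile$amp_slope_per_db)
  y <- numeric(n_samples)
  if (gain <= 0) return(y)
  ears <- if (spec$ear == "both") c("left", "right") else spec$ear
  for (ear in ears) {
    delay <- ear_delay_ms(ear, spec$itd_ms)
    for (i in 1:4) {
      y <- y + biphasic_kernel(t, profile$wave_latency_ms[i] + delay,
                               profile$wave_width_ms[i],
                               profile$wave_amplitude_av[i] * gain)
    }
  }
  if (spec$ear == "both") {
    tr <- dn1_truth_at(profile, spec$itd_ms, gain)
    y <- y + dn1_kernel(t, tr$latency_ms, profile$dn1$width_ms,
                        tr$amplitude_av)
  }
  y
}

#' Generative wave truth for a condition
#'
#' Per-wave peak/trough truth measured on the sample grid from each wave's
#' isolated kernel (neighbouring-wave tails are below 1e-9 aV at the default
#' spacing, so these match extrema of the full noiseless trace).
#'
#' @inheritParams noiseless_trace
#' @return data frame with one row per wave: `wave`, `peak_latency_ms`,
#'   `peak_value_av`, `trough_latency_ms`, `trough_value_av`,
#'   `amplitude_av`.  Waves with zero generative amplitude (at or below
#'   threshold) carry `amplitude_av = 0` and `NA` latencies.
#' @export
true_waves <- function(profile, spec, fs = ABR_FS, n_samples = ABR_N_SAMPLES) {
  t <- abr_time_ms(n_samples, fs)
  gain <- level_gain(spec$level, profile_threshold(profile, spec),
                     profile$amp_slope_per_db)
  delay <- if (spec$ear == "both") 0 else ear_delay_ms(spec$ear, spec$itd_ms)
  out <- data.frame(wave = c("I", "II", "III", "IV"),
                    peak_latency_ms = NA_real_, peak_value_av = NA_real_,
                    trough_latency_ms = NA_real_, trough_value_av = NA_real_,
                    amplitude_av = 0)
  if (gain <= 0) return(out)
  n_ear <- if (spec$ear == "both") 2 else 1
  for (i in 1:4) {
    a <- profile$wave_amplitude_av[i] * gain * n_ear
    w <- profile$wave_width_ms[i]
    lat <- profile$wave_latency_ms[i] + delay
    y <- biphasic_kernel(t, lat, w, a)
    ip <- which.max(y)
    search_end <- min(n_samples, ip + ceiling(4 * w / 1000 * fs))
    it <- ip + which.min(y[(ip + 1):search_end])
    out[i, -1] <- list(t[ip], y[ip], t[it], y[it], y[ip] - y[it])
  }
  out
}

#' Generative DN1 truth for one binaural condition
#'
#' @inheritParams noiseless_trace
#' @return list with `latency_ms` (analytic trough latency) and
#'   `amplitude_av` (magnitude of the negative deflection).
#' @export
true_dn1 <- function(profile, spec) {
  stopifnot(spec$ear == "both")
  gain <- level_gain(spec$level, profile_threshold(profile, spec),
                     profile$amp_slope_per_db)
  dn1_truth_at(profile, spec$itd_ms, gain)
}

## ---- epoch synthesis -------------------------------------------------------

heartbeat_artifact <- function(t_ms, center_ms, amplitude_av) {
  amplitude_av * sin(2 * pi * (t_ms - center_ms) / 3) *
    exp(-((t_ms - center_ms) / 1.5)^2)
}

#' Synthesize one epoch
#'
#' One raw repetition: the noiseless evoked trace plus white background
#' noise, plus (with probability `noise$artifact_rate`) a heartbeat-like
#' high-amplitude transient.  Uses the current RNG state.
#'
#' @inheritParams noiseless_trace
#' @param noise [noise_model()] object.
#' @return object of class `abr_epoch`: list with `samples`, `fs`, `spec`,
#'   `animal` and logical `artifact`.
#' @export
synth_epoch <- function(spec, profile, noise = noise_model(),
                        fs = ABR_FS, n_samples = ABR_N_SAMPLES,
                        .base = NULL) {
  base <- if (is.null(.base)) noiseless_trace(profile, spec, fs, n_samples)
          else .base
  artifact <- noise$artifact_rate > 0 && stats::runif(1) < noise$artifact_rate
  y <- base
  if (noise$background_sd_av > 0) {
    y <- y + stats::rnorm(n_samples, 0, noise$background_sd_av)
  }
  if (artifact) {
    center <- stats::runif(1, 1.5, ABR_WINDOW_MS - 1.5)
    y <- y + heartbeat_artifact(abr_time_ms(n_samples, fs), center,
                                noise$artifact_amplitude_av)
  }
  structure(
    list(samples = y, fs = fs, spec = spec, animal = profile$id,
         artifact = artifact),
    class = "abr_epoch"
  )
}

#' Synthesize a binaural epoch
#'
#' Convenience wrapper around [synth_epoch()] that insists on a binaural
#' stimulus with an ITD.
#'
#' @inheritParams synth_epoch
#' @export
synth_binaural_epoch <- function(spec, profile, noise = noise_model(),
                                 fs = ABR_FS, n_samples = ABR_N_SAMPLES) {
  if (spec$ear != "both" || is.null(spec$itd_ms)) {
    stop("binaural synthesis requires ear = \"both\" with an ITD",
         call. = FALSE)
  }
  synth_epoch(spec, profile, noise, fs, n_samples)
}

#' Synthesize a set of epochs for one condition
#'
#' @inheritParams synth_epoch
#' @param n_epochs number of repetitions.
#' @param seed optional integer; when given, the RNG is seeded so the set is
#'   exactly reproducible.
#' @return object of class `abr_epochs`: `samples` is an
#'   `n_samples x n_epochs` matrix; `artifact_epochs` records the generative
#'   bookkeeping of which repetitions carry an injected artifact.
#' @export
synth_epochs <- function(spec, profile, n_epochs, noise = noise_model(),
                         seed = NULL, fs = ABR_FS,
                         n_samples = ABR_N_SAMPLES) {
  stopifnot(n_epochs >= 1)
  if (!is.null(seed)) set.seed(seed)
  base <- noiseless_trace(profile, spec, fs, n_samples)
  m <- matrix(0, nrow = n_samples, ncol = n_epochs)
  artifact <- logical(n_epochs)
  for (k in seq_len(n_epochs)) {
    e <- synth_epoch(spec, profile, noise, fs, n_samples, .base = base)
    m[, k] <- e$samples
    artifact[k] <- e$artifact
  }
  abr_epochs(m, fs = fs, spec = spec, animal = profile$id,
             artifact_epochs = which(artifact))
}

#' Epoch-set container
#'
#' @param samples numeric matrix, samples by repetitions.
#' @param fs sampling rate (Hz).
#' @param spec [stimulus_spec()] for the shared condition.
#' @param animal animal identifier.
#' @param artifact_epochs integer indices of artifact-bearing repetitions
#'   (generative bookkeeping; empty for real data).
#' @return object of class `abr_epochs`.
#' @export
abr_epochs <- function(samples, fs = ABR_FS, spec = NULL, animal = NA_character_,
                       artifact_epochs = integer()) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  structure(
    list(samples = samples, fs = fs, spec = spec, animal = animal,
         artifact_epochs = as.integer(artifact_epochs)),
    class = "abr_epochs"
  )
}

#' @export
print.abr_epochs <- function(x, ...) {
  cat(sprintf("<abr_epochs> %d epochs x %d samples, fs = %g Hz, animal = %s\n",
              ncol(x$samples), nrow(x$samples), x$fs, x$animal))
  if (length(x$artifact_epochs)) {
    cat(sprintf("  %d artifact-bearing epochs (generative truth)\n",
                length(x$artifact_epochs)))
  }
  invisible(x)
}

#' Directly synthesize an averaged trace
#'
#' Equivalent in distribution to averaging `n_reps` artifact-free epochs:
#' the noiseless trace plus white noise with SD
#' `background_sd_av / sqrt(n_reps)`.  Used where epoch-level synthesis
#' would only burn time (Monte-Carlo studies); the epoch route and this
#' shortcut agree by construction of the white-noise model.
#'
#' @inheritParams synth_epoch
#' @param n_reps nominal number of averaged repetitions.
#' @return an `abr_trace` (see [abr_trace()]).
#' @export
synth_averaged_trace <- function(spec, profile, noise = noise_model(),
                                 n_reps = 500, fs = ABR_FS,
                                 n_samples = ABR_N_SAMPLES) {
  y <- noiseless_trace(profile, spec, fs, n_samples)
  sd_avg <- noise$background_sd_av / sqrt(n_reps)
  if (sd_avg > 0) y <- y + stats::rnorm(n_samples, 0, sd_avg)
  abr_trace(y, fs = fs, spec = spec, animal = profile$id,
            n_accepted = n_reps, n_rejected = 0L,
            provenance = list(synthesized = "averaged",
                              background_sd_av = noise$background_sd_av))
}
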