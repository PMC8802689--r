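# Cohort-level synthesis and analysis: realize a sex-by-genotype cohort
# with generative truth tables, then run the full measurement pipeline
# (preprocess -> peaks -> audiogram -> BIC) to produce the long-format
# tables the statistics layer consumes.

#' Default cohort design
#'
#' The five observed sex-by-genotype groups: wild-type (B6) and Fmr1 mutant
#' males; B6, homozygous Fmr1 and heterozygous Fmr1 females (the mutation
#' is X-linked, so heterozygotes are female only).
#' @return data frame with `sex` and `genotype`.
#' @export
default_design <- function() {
  data.frame(
    sex = c("female", "female", "female", "male", "male"),
    genotype = c("B6", "Fmr1", "Fmr1 het", "B6", "Fmr1")
  )
}

#' Cohort stimulus conditions
#'
#' Which conditions each animal is run through: monaural clicks in both
#' ears, binaural clicks across the ITD grid, and tone series across
#' frequencies and descending levels.
#'
#' @param clicks include monaural click conditions?
#' @param click_level_db click level (dB SPL).
#' @param itds ITD grid for binaural series (ms); `NULL` to skip binaural.
#' @param frequencies_khz audiogram tone frequencies; `NULL` to skip tones.
#' @param levels_db descending tone levels (dB SPL, steps of 5-10).
#' @return a named list of class `abr_conditions`.
#' @export
cohort_conditions <- function(clicks = TRUE, click_level_db = 90,
                              itds = itd_grid_ms(),
                              frequencies_khz = tone_frequencies_khz(),
                              levels_db = seq(90, 20, by = -5)) {
  if (!is.null(itds) && !all(vapply(itds, function(x)
    any(abs(x - itd_grid_ms()) < 1e-9), logical(1)))) {
    stop("ITDs must lie on the ±2 ms grid in 0.5 ms steps", call. = FALSE)
  }
  if (!is.null(frequencies_khz) && length(levels_db)) {
    if (length(levels_db) < 2 || any(diff(levels_db) >= 0)) {
      stop("`levels_db` must be strictly descending", call. = FALSE)
    }
    step <- abs(diff(levels_db))
    if (any(step < 5 - 1e-9 | step > 10 + 1e-9)) {
      stop("level steps must lie in [5, 10] dB SPL", call. = FALSE)
    }
  }
  structure(list(clicks = clicks, click_level_db = click_level_db,
                 itds = itds, frequencies_khz = frequencies_khz,
                 levels_db = levels_db),
            class = "abr_conditions")
}

#' Synthesize a cohort
#'
#' Realizes `n_per_group` animals per design group (profiles, litter
#' assignment, morphometrics), enumerates every trace to be recorded
#' (clicks, binaural ITD triplets, tone level series) with a deterministic
#' per-trace seed, and emits the generative truth tables used as oracles
#' downstream.  Epochs/traces themselves are realized lazily with
#' [realize_trace()] so arbitrarily large cohorts stay cheap to hold.
#'
#' @param n_per_group animals per sex-by-genotype group (>= 2).
#' @param design data frame of `sex`, `genotype` groups, see
#'   [default_design()].
#' @param kernels,effects,noise,dn1 generator parameter objects.
#' @param conditions a [cohort_conditions()] list.
#' @param n_reps repetitions averaged per condition (the recording
#'   convention is 500-1000; scale down for simulation studies).
#' @param mode `"trace"` realizes averaged traces directly (equivalent in
#'   distribution for artifact-free noise); `"epoch"` realizes raw epoch
#'   sets including artifacts for the full preprocessing path.
#' @param seed integer seed; the whole cohort is a pure function of it.
#' @return object of class `abr_cohort`.
#' @export
synth_cohort <- function(n_per_group = 8, design = default_design(),
                         kernels = wave_kernels(),
                         effects = group_effects(),
                         noise = noise_model(),
                         dn1 = dn1_params(),
                         conditions = cohort_conditions(),
                         n_reps = 500,
                         mode = c("trace", "epoch"),
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_per_group >= 2)
  if (nrow(design) == 0) stop("empty design", call. = FALSE)
  set.seed(seed)

  animals <- list(); profiles <- list()
  idx <- 0L
  for (g in seq_len(nrow(design))) {
    for (k in seq_len(n_per_group)) {
      idx <- idx + 1L
      id <- sprintf("a%03d", idx)
      litter <- sample(c("mixed", "single"), 1)
      profile <- animal_profile(id, sex = design$sex[g],
                                genotype = design$genotype[g],
                                litter = litter, kernels = kernels,
                                effects = effects, dn1 = dn1)
      weight_mu <- if (design$sex[g] == "male") 27 else 22
      animals[[idx]] <- data.frame(
        animal = id, sex = design$sex[g], genotype = design$genotype[g],
        litter = litter,
        pinna_width_mm = stats::rnorm(1, 9, 0.4),
        pinna_length_mm = stats::rnorm(1, 12, 0.5),
        interpinna_mm = stats::rnorm(1, 18, 0.8),
        nose_to_pinna_mm = stats::rnorm(1, 22, 1.0),
        weight_g = stats::rnorm(1, weight_mu, 2)
      )
      profiles[[id]] <- profile
    }
  }
  animals <- morphology_table(do.call(rbind, animals))

  # enumerate traces with deterministic per-trace seeds
  rows <- list(); n <- 0L
  add <- function(animal, type, ear, level, freq, itd) {
    n <<- n + 1L
    rows[[n]] <<- data.frame(animal = animal, type = type, ear = ear,
                             level_db = level,
                             frequency_khz = ifelse(is.null(freq), NA, freq),
                             itd_ms = ifelse(is.null(itd), NA, itd))
  }
  for (id in names(profiles)) {
    if (isTRUE(conditions$clicks)) {
      add(id, "click", "left", conditions$click_level_db, NULL, NULL)
      add(id, "click", "right", conditions$click_level_db, NULL, NULL)
    }
    for (itd in conditions$itds) {
      add(id, "bic", "left", conditions$click_level_db, NULL, itd)
      add(id, "bic", "right", conditions$click_level_db, NULL, itd)
      add(id, "bic", "both", conditions$click_level_db, NULL, itd)
    }
    for (f in conditions$frequencies_khz) {
      for (lv in conditions$levels_db) add(id, "tone", "left", lv, f, NULL)
    }
  }
  trace_table <- if (n > 0) do.call(rbind, rows) else {
    data.frame(animal = character(), type = character(), ear = character(),
               level_db = numeric(), frequency_khz = numeric(),
               itd_ms = numeric())
  }
  trace_table$seed <- (seed %% 100000L) * 10000L + seq_len(nrow(trace_table))

  truth <- cohort_truth(profiles, conditions)

  structure(
    list(animals = animals, profiles = profiles, trace_table = trace_table,
         truth = truth,
         params = list(kernels = kernels, effects = effects, noise = noise,
                       dn1 = dn1, conditions = conditions, n_reps = n_reps,
                       mode = mode, seed = seed)),
    class = "abr_cohort"
  )
}

# Generative truth tables for every condition of every animal.
cohort_truth <- function(profiles, conditions) {
  waves <- list(); thresholds <- list(); dn1s <- list()
  for (id in names(profiles)) {
    p <- profiles[[id]]
    meta <- data.frame(animal = id, sex = p$sex, genotype = p$genotype,
                       litter = p$litter)
    if (isTRUE(conditions$clicks)) {
      spec <- stimulus_spec("click", "left", conditions$click_level_db)
      waves[[id]] <- cbind(meta, true_waves(p, spec))
    }
    thresholds[[id]] <- cbind(
      meta,
      data.frame(frequency_khz = as.numeric(names(p$thresholds_db)),
                 threshold_db = unname(p$thresholds_db)),
      row.names = NULL
    )
    if (length(conditions$itds)) {
      rows <- lapply(conditions$itds, function(itd) {
        spec <- stimulus_spec("click", "both", conditions$click_level_db,
                              itd_ms = itd)
        tr <- true_dn1(p, spec)
        data.frame(itd_ms = itd, latency_ms = tr$latency_ms,
                   amplitude_av = tr$amplitude_av)
      })
      dn1s[[id]] <- cbind(meta, do.call(rbind, rows), row.names = NULL)
    }
  }
  list(
    waves = if (length(waves)) do.call(rbind, c(waves, make.row.names = FALSE)),
    thresholds = do.call(rbind, c(thresholds, make.row.names = FALSE)),
    dn1 = if (length(dn1s)) do.call(rbind, c(dn1s, make.row.names = FALSE))
  )
}

#' @export
print.abr_cohort <- function(x, ...) {
  cat(sprintf("<abr_cohort> %d animals, %d traces to realize (%s mode, seed %d)\n",
              nrow(x$animals), nrow(x$trace_table), x$params$mode,
              x$params$seed))
  print(table(x$animals$sex, x$animals$genotype))
  invisible(x)
}

row_spec <- function(row) {
  stimulus_spec(
    modality = if (row$type == "tone") "tone" else "click",
    ear = row$ear,
    level = row$level_db,
    frequency_khz = if (is.na(row$frequency_khz)) NULL else row$frequency_khz,
    itd_ms = if (is.na(row$itd_ms)) NULL else row$itd_ms
  )
}

#' Realize one enumerated cohort trace
#'
#' Deterministic given the cohort: the enumerated per-trace seed is set
#' before synthesis.  In `"trace"` mode returns an averaged [abr_trace()];
#' in `"epoch"` mode an [abr_epochs()] set (including artifact truth).
#'
#' @param cohort an [synth_cohort()] object.
#' @param i row index into `cohort$trace_table`.
#' @export
realize_trace <- function(cohort, i) {
  row <- cohort$trace_table[i, ]
  spec <- row_spec(row)
  profile <- cohort$profiles[[row$animal]]
  if (cohort$params$mode == "trace") {
    set.seed(row$seed)
    synth_averaged_trace(spec, profile, cohort$params$noise,
                         n_reps = cohort$params$n_reps)
  } else {
    synth_epochs(spec, profile, cohort$params$n_reps, cohort$params$noise,
                 seed = row$seed)
  }
}

## ---- cohort analysis -------------------------------------------------------

#' Analysis settings for a cohort run
#'
#' @param preprocess a [preprocess_settings()] list.
#' @param windows per-wave detection windows; `NULL` derives them from the
#'   cohort's kernel latencies.
#' @param min_prominence peak-detection prominence floor (aV); `NULL` for
#'   the per-trace default.
#' @param audiometry list: `criterion_multiple`, `window_ms`, `method`
#'   (see [estimate_threshold()]).
#' @param binaural list: `half_window_ms`, `noise_floor_multiple`.
#' @return a named list of class `abr_analysis_settings`.
#' @export
analysis_settings <- function(preprocess = preprocess_settings(),
                              windows = NULL, min_prominence = NULL,
                              audiometry = list(criterion_multiple = 2,
                                                window_ms = c(1, 6),
                                                method = "template"),
                              binaural = list(half_window_ms = 1.5,
                                              noise_floor_multiple = 3)) {
  structure(list(preprocess = preprocess, windows = windows,
                 min_prominence = min_prominence, audiometry = audiometry,
                 binaural = binaural),
            class = "abr_analysis_settings")
}

cohort_processed_trace <- function(cohort, i, settings) {
  x <- realize_trace(cohort, i)
  if (inherits(x, "abr_epochs")) {
    preprocess_epochs(x, settings$preprocess)
  } else {
    preprocess_trace(x, settings$preprocess)
  }
}

#' Run the full measurement pipeline over a cohort
#'
#' For every animal: preprocess and quantify the monaural click traces
#' (wave I-IV amplitudes/latencies averaged across ears), estimate the
#' audiogram from the tone level series, and extract the DN1 series across
#' ITDs.  Returns the long-format tables consumed by the statistics layer,
#' with generative truth left untouched in `cohort$truth`.
#'
#' @param cohort an [synth_cohort()] object.
#' @param settings an [analysis_settings()] list.
#' @return object of class `abr_results`: list of data frames `monaural`,
#'   `audiogram`, `bic`, `morphology`.
#' @export
analyze_cohort <- function(cohort, settings = analysis_settings()) {
  stopifnot(inherits(cohort, "abr_cohort"))
  tt <- cohort$trace_table
  windows <- if (is.null(settings$windows)) {
    wave_windows(cohort$params$kernels$base_latency_ms)
  } else settings$windows
  meta <- cohort$animals[, c("animal", "sex", "genotype", "litter")]

  monaural <- list(); audiogram <- list(); bic <- list()
  for (id in unique(tt$animal)) {
    m <- meta[meta$animal == id, ]

    ## monaural clicks
    li <- which(tt$animal == id & tt$type == "click" & tt$ear == "left")
    ri <- which(tt$animal == id & tt$type == "click" & tt$ear == "right")
    if (length(li) && length(ri)) {
      pl <- detect_peaks(cohort_processed_trace(cohort, li, settings),
                         windows, settings$min_prominence)
      pr <- detect_peaks(cohort_processed_trace(cohort, ri, settings),
                         windows, settings$min_prominence)
      monaural[[id]] <- cbind(m, monaural_summary(pl, pr),
                              row.names = NULL)
    }

    ## audiogram tone series
    freqs <- unique(tt$frequency_khz[tt$animal == id & tt$type == "tone"])
    freqs <- freqs[!is.na(freqs)]
    if (length(freqs)) {
      series <- lapply(freqs, function(f) {
        rows <- which(tt$animal == id & tt$type == "tone" &
                        tt$frequency_khz == f)
        levels <- tt$level_db[rows]
        ord <- order(levels, decreasing = TRUE)
        list(traces = lapply(rows[ord], cohort_processed_trace,
                             cohort = cohort, settings = settings),
             levels = levels[ord])
      })
      names(series) <- as.character(freqs)
      ag <- build_audiogram(
        series,
        criterion_multiple = settings$audiometry$criterion_multiple,
        window_ms = settings$audiometry$window_ms,
        method = settings$audiometry$method
      )
      audiogram[[id]] <- cbind(m, as.data.frame(ag), row.names = NULL)
    }

    ## binaural ITD series
    itds <- unique(tt$itd_ms[tt$animal == id & tt$type == "bic"])
    itds <- itds[!is.na(itds)]
    if (length(itds)) {
      triplets <- lapply(itds, function(itd) {
        get_role <- function(ear) {
          i <- which(tt$animal == id & tt$type == "bic" & tt$ear == ear &
                       tt$itd_ms == itd)
          cohort_processed_trace(cohort, i, settings)
        }
        list(left = get_role("left"), right = get_role("right"),
             binaural = get_role("both"))
      })
      series <- bic_itd_series(
        triplets, windows = windows,
        min_prominence = settings$min_prominence,
        half_window_ms = settings$binaural$half_window_ms,
        noise_floor_multiple = settings$binaural$noise_floor_multiple
      )
      bic[[id]] <- cbind(m, as.data.frame(series), row.names = NULL)
    }
  }

  structure(
    list(
      monaural = if (length(monaural))
        do.call(rbind, c(monaural, make.row.names = FALSE)),
      audiogram = if (length(audiogram))
        do.call(rbind, c(audiogram, make.row.names = FALSE)),
      bic = if (length(bic)) do.call(rbind, c(bic, make.row.names = FALSE)),
      morphology = cohort$animals
    ),
    class = "abr_results"
  )
}

#' @export
print.abr_results <- function(x, ...) {
  cat("<abr_results>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}
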