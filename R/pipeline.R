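# End-to-end pipeline: configuration -> synthetic cohort -> preprocessing
# -> waveform metrics / audiometry / binaural series -> statistics ->
# result bundle on disk.

config_effects <- function(cfg) {
  as_named <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    unlist(x)
  }
  group_effects(
    wave4_amp_multiplier = as_named(cfg$wave4_amp_multiplier),
    dn1_latency_shift_ms = as_named(cfg$dn1_latency_shift_ms),
    highfreq_threshold_shift_db = as_named(cfg$highfreq_threshold_shift_db),
    animal_sd_av = cfg$animal_sd_av %||% 0.1
  )
}

config_cohort <- function(config) {
  cond <- config$conditions
  synth_cohort(
    n_per_group = config$cohort$n_per_group,
    effects = config_effects(config$effects),
    noise = noise_model(config$noise$background_sd_av,
                        config$noise$artifact_rate,
                        config$noise$artifact_amplitude_av),
    conditions = cohort_conditions(
      clicks = isTRUE(cond$clicks),
      click_level_db = cond$click_level_db,
      itds = cond$itds,
      frequencies_khz = cond$frequencies_khz,
      levels_db = cond$levels_db),
    n_reps = config$cohort$n_reps,
    mode = config$cohort$mode,
    seed = config$seed
  )
}

config_analysis_settings <- function(config) {
  pp <- config$preprocessing
  analysis_settings(
    preprocess = preprocess_settings(
      reject_threshold_av = pp$reject_threshold_av,
      filter = isTRUE(pp$filter),
      low_hz = pp$low_hz, high_hz = pp$high_hz, order = pp$order),
    audiometry = list(
      criterion_multiple = config$audiometry$criterion_multiple,
      window_ms = config$audiometry$window_ms,
      method = config$audiometry$method),
    binaural = list(
      half_window_ms = config$binaural$half_window_ms,
      noise_floor_multiple = config$binaural$noise_floor_multiple)
  )
}

#' Statistics stage over cohort result tables
#'
#' Fits the mixed model and extracts pairwise genotype-within-sex marginal
#' mean contrasts for each available measurement table (monaural amplitude
#' and latency across waves, DN1 amplitude and latency across ITDs,
#' audiogram thresholds across frequencies), and two-way ANOVAs for weight
#' and effective pinna diameter.
#'
#' @param results an [analyze_cohort()] result.
#' @return named list of `abr_contrasts` / ANOVA summary data frames.
#' @export
run_stats <- function(results) {
  out <- list()
  try_fit <- function(table, response, condition) {
    tryCatch({
      fit <- fit_mixed_model(table, response, condition)
      pairwise_emmeans(fit, by = "sex")
    }, error = function(e) {
      data.frame(error = conditionMessage(e))
    })
  }
  if (!is.null(results$monaural)) {
    out$monaural_amplitude <- try_fit(results$monaural, "amplitude_av", "wave")
    out$monaural_latency <- try_fit(results$monaural, "latency_ms", "wave")
  }
  if (!is.null(results$bic)) {
    tab <- results$bic
    tab$itd <- factor(tab$itd_ms)
    out$bic_amplitude <- try_fit(tab, "amplitude_av", "itd")
    out$bic_latency <- try_fit(tab, "latency_ms", "itd")
  }
  if (!is.null(results$audiogram)) {
    tab <- results$audiogram
    tab$frequency <- factor(tab$frequency_khz)
    out$audiogram <- try_fit(tab, "threshold_db", "frequency")
  }
  if (!is.null(results$morphology)) {
    for (resp in c("weight_g", "effective_diameter_mm")) {
      an <- anova_two_way(results$morphology, resp)
      tab <- as.data.frame(an$table)
      tab$term <- trimws(rownames(tab))
      names(tab) <- c("df", "sum_sq", "mean_sq", "f_value", "p_value", "term")
      out[[paste0("anova_", resp)]] <- tab[, c("term", "df", "sum_sq",
                                               "mean_sq", "f_value",
                                               "p_value")]
    }
  }
  out
}

#' Run the full pipeline from a configuration
#'
#' Synthesizes (or re-synthesizes, deterministically) the configured
#' cohort, runs preprocessing, waveform metrics, audiometry and the
#' binaural series, then the statistics layer, and writes the result
#' bundle.  Identical configuration and seed yield byte-identical output
#' files.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param seed optional override of `config$seed`.
#' @param out optional output directory; when `NULL` nothing is written.
#' @return invisible list with `results` (measurement tables), `stats`
#'   (contrast tables), `cohort` and the effective `config`.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL, out = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(out)) out <- config$out

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("synth", config_cohort(config))
  settings <- config_analysis_settings(config)
  results <- stage("analyze", analyze_cohort(cohort, settings))
  stats <- if (isTRUE(config$stats)) stage("stats", run_stats(results))
           else list()
  if (!is.null(out)) {
    cfg_flat <- config
    cfg_flat$out <- NULL
    stage("write", write_results(
      results, out, stats = stats,
      provenance = list(package = "abrkit",
                        version = as.character(utils::packageVersion("abrkit")),
                        seed = config$seed, config = cfg_flat)))
  }
  invisible(list(results = results, stats = stats, cohort = cohort,
                 config = config))
}
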