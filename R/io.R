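# File formats: trace and epoch-set CSVs with JSON sidecars, cohort
# manifests, YAML run configuration.  All files are UTF-8, '.' decimal,
# with units in every header; numeric formatting is canonical (%.10g) so
# that write(read(x)) round-trips byte-for-byte.

fmt_num <- function(x) sprintf("%.10g", x)

CSV_HEADER <- "time_ms,voltage_aV"

write_samples_csv <- function(samples, fs, path) {
  t <- abr_time_ms(length(samples), fs)
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(c(CSV_HEADER, paste(fmt_num(t), fmt_num(samples), sep = ",")),
             con, sep = "\n")
}

read_samples_csv <- function(path, fs) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || lines[1] != CSV_HEADER) {
    stop("format error in ", basename(path),
         ": header must be '", CSV_HEADER, "' (units are mandatory)",
         call. = FALSE)
  }
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  t <- as.numeric(vapply(parts, `[`, character(1), 1))
  v <- as.numeric(vapply(parts, `[`, character(1), 2))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("non-finite voltage sample at row ", bad[1], " of ",
         basename(path), call. = FALSE)
  }
  if (length(t) > 1) {
    dt <- stats::median(diff(t))
    if (abs(dt - 1000 / fs) > 1e-6 * (1000 / fs)) {
      stop("sampling-rate mismatch in ", basename(path),
           sprintf(": time step %.6g ms vs declared fs %g Hz", dt, fs),
           call. = FALSE)
    }
  }
  v
}

stimulus_to_list <- function(spec) {
  if (is.null(spec)) return(NULL)
  spec[!vapply(spec, is.null, logical(1))]
}

stimulus_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  stimulus_spec(modality = x$modality, ear = x$ear, level = x$level,
                frequency_khz = x$frequency_khz, itd_ms = x$itd_ms,
                isi_mean_ms = x$isi_mean_ms %||% 30,
                isi_sd_ms = x$isi_sd_ms %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_canonical <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             con, sep = "\n")
}

## ---- single trace ----------------------------------------------------------

#' Write / read one averaged trace
#'
#' A trace is a CSV (`time_ms,voltage_aV`, one row per sample) plus a JSON
#' sidecar (`<prefix>.json`) carrying the sampling rate, the stimulus
#' descriptor, animal metadata and the processing provenance.
#'
#' @param trace an [abr_trace()].
#' @param prefix file path without extension.
#' @param meta optional named list merged into the sidecar (e.g. sex,
#'   genotype).
#' @return `write_trace()` returns `prefix` invisibly; `read_trace()`
#'   returns the [abr_trace()] with the sidecar metadata in
#'   `attr(, "meta")`.
#' @export
write_trace <- function(trace, prefix, meta = list()) {
  stopifnot(inherits(trace, "abr_trace"))
  write_samples_csv(trace$samples, trace$fs, paste0(prefix, ".csv"))
  sidecar <- c(list(format = "abrkit-trace-v1", fs_hz = trace$fs,
                    animal = trace$animal,
                    n_accepted = trace$n_accepted,
                    n_rejected = trace$n_rejected,
                    stimulus = stimulus_to_list(trace$spec),
                    provenance = trace$provenance),
               meta)
  write_json_canonical(sidecar, paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_trace
#' @export
read_trace <- function(prefix) {
  sidecar_path <- paste0(prefix, ".json")
  if (!file.exists(sidecar_path)) {
    stop("format error: missing sidecar JSON ", basename(sidecar_path),
         call. = FALSE)
  }
  side <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  fs <- side$fs_hz
  samples <- read_samples_csv(paste0(prefix, ".csv"), fs)
  tr <- abr_trace(samples, fs = fs,
                  spec = stimulus_from_list(side$stimulus),
                  animal = side$animal %||% NA_character_,
                  n_accepted = side$n_accepted %||% 1L,
                  n_rejected = side$n_rejected %||% 0L,
                  provenance = side$provenance %||% list())
  attr(tr, "meta") <- side
  tr
}

## ---- epoch sets ------------------------------------------------------------

#' Write / read an epoch set
#'
#' An epoch set is a directory with one CSV per repetition
#' (`epoch_0001.csv`, ...) and a `sidecar.json` with the stimulus, animal,
#' sampling rate and the artifact bookkeeping (when synthetic).
#'
#' @param epochs an [abr_epochs()] set.
#' @param dir directory to create.
#' @return `write_epoch_set()` returns `dir` invisibly; `read_epoch_set()`
#'   the [abr_epochs()].
#' @export
write_epoch_set <- function(epochs, dir) {
  stopifnot(inherits(epochs, "abr_epochs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(epochs$samples)
  files <- sprintf("epoch_%04d.csv", seq_len(n))
  for (k in seq_len(n)) {
    write_samples_csv(epochs$samples[, k], epochs$fs, file.path(dir, files[k]))
  }
  write_json_canonical(
    list(format = "abrkit-epochs-v1", fs_hz = epochs$fs,
         animal = epochs$animal, n_epochs = n, files = files,
         stimulus = stimulus_to_list(epochs$spec),
         artifact_epochs = epochs$artifact_epochs),
    file.path(dir, "sidecar.json"))
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  sidecar_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sidecar_path)) {
    stop("format error: missing sidecar JSON in ", dir, call. = FALSE)
  }
  side <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  cols <- lapply(side$files, function(f) {
    read_samples_csv(file.path(dir, f), side$fs_hz)
  })
  abr_epochs(do.call(cbind, cols), fs = side$fs_hz,
             spec = stimulus_from_list(side$stimulus),
             animal = side$animal %||% NA_character_,
             artifact_epochs = side$artifact_epochs %||% integer())
}

## ---- cohort data directories -----------------------------------------------

#' Write a synthesized cohort to disk
#'
#' Creates `dir/` with `manifest.json` (animals, trace enumeration,
#' generator settings), `truth.json` (generative truth tables) and a
#' `traces/` tree: per enumerated trace either `tNNNNN.csv` + sidecar
#' (trace mode) or a `tNNNNN/` epoch directory (epoch mode).
#'
#' @param cohort an [synth_cohort()] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_data <- function(cohort, dir) {
  stopifnot(inherits(cohort, "abr_cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  tt <- cohort$trace_table
  tt$file <- sprintf("t%05d", seq_len(nrow(tt)))
  for (i in seq_len(nrow(tt))) {
    x <- realize_trace(cohort, i)
    m <- cohort$animals[cohort$animals$animal == tt$animal[i],
                        c("sex", "genotype", "litter")]
    if (inherits(x, "abr_epochs")) {
      write_epoch_set(x, file.path(dir, "traces", tt$file[i]))
    } else {
      write_trace(x, file.path(dir, "traces", tt$file[i]),
                  meta = list(sex = m$sex, genotype = m$genotype,
                              litter = m$litter, type = tt$type[i]))
    }
  }
  write_json_canonical(
    list(format = "abrkit-cohort-v1",
         mode = cohort$params$mode,
         seed = cohort$params$seed,
         n_reps = cohort$params$n_reps,
         animals = cohort$animals,
         trace_table = tt),
    file.path(dir, "manifest.json"))
  write_json_canonical(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a cohort data directory
#'
#' Round-trip counterpart of [write_cohort_data()]: returns the manifest
#' tables plus a `get_trace(i)` accessor that reads and returns trace `i`
#' (an [abr_trace()] or [abr_epochs()] depending on the stored mode).
#'
#' @param dir directory written by [write_cohort_data()].
#' @export
read_cohort_data <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("format error: missing manifest.json in ", dir, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  tt <- manifest$trace_table
  get_trace <- function(i) {
    path <- file.path(dir, "traces", tt$file[i])
    if (manifest$mode == "epoch") read_epoch_set(path) else read_trace(path)
  }
  list(manifest = manifest, animals = manifest$animals,
       trace_table = tt, get_trace = get_trace,
       truth = if (file.exists(file.path(dir, "truth.json"))) {
         jsonlite::fromJSON(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
       })
}

## ---- results ---------------------------------------------------------------

write_table_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(df[[j]]), "NA", fmt_num(df[[j]]))
  }
  writeLines(c(paste(names(out), collapse = ","),
               do.call(paste, c(lapply(out, as.character), sep = ","))),
             con, sep = "\n")
}

#' Write analysis result tables
#'
#' Emits one CSV per table (`monaural.csv`, `audiogram.csv`, `bic.csv`,
#' `morphology.csv`, plus any statistics tables) and a `provenance.json`
#' recording the run configuration and seed.  Output is deterministic:
#' identical inputs yield byte-identical files.
#'
#' @param results an [analyze_cohort()] result.
#' @param dir output directory.
#' @param stats optional named list of additional data frames (contrast
#'   tables) written as `stats_<name>.csv`.
#' @param provenance named list stored as `provenance.json`.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, stats = list(), provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    if (!is.null(results[[nm]]) && is.data.frame(results[[nm]])) {
      write_table_csv(as.data.frame(results[[nm]]),
                      file.path(dir, paste0(nm, ".csv")))
    }
  }
  for (nm in names(stats)) {
    write_table_csv(as.data.frame(stats[[nm]]),
                    file.path(dir, paste0("stats_", nm, ".csv")))
  }
  write_json_canonical(provenance, file.path(dir, "provenance.json"))
  invisible(dir)
}

## ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' The complete configuration tree with every tunable setting at its
#' default; [read_config()] merges a user YAML over this.
#' @export
default_config <- function() {
  list(
    seed = 1,
    cohort = list(n_per_group = 8, mode = "trace", n_reps = 500),
    conditions = list(clicks = TRUE, click_level_db = 90,
                      itds = itd_grid_ms(),
                      frequencies_khz = tone_frequencies_khz(),
                      levels_db = seq(90, 20, by = -5)),
    effects = list(wave4_amp_multiplier = NULL,
                   dn1_latency_shift_ms = NULL,
                   highfreq_threshold_shift_db = NULL,
                   animal_sd_av = 0.1),
    noise = list(background_sd_av = 1.0, artifact_rate = 0.05,
                 artifact_amplitude_av = 20),
    preprocessing = list(reject_threshold_av = NULL, filter = TRUE,
                         low_hz = 50, high_hz = 3000, order = 2),
    audiometry = list(criterion_multiple = 2, method = "template",
                      window_ms = c(1, 6)),
    binaural = list(half_window_ms = 1.5, noise_floor_multiple = 3),
    stats = TRUE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take defaults from
#' [default_config()].  `write_config()` serializes a configuration such
#' that reading it back yields an identical object.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), c(names(base), "out"))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merge_config(base, user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
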