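# Epoch preprocessing: artifact rejection, averaging, zero-phase band-pass
# filtering and baseline zeroing.  Pipeline order is fixed:
# reject -> average -> filter -> zero.

#' Averaged-trace container
#'
#' One processed evoked-potential waveform for a stimulus condition.
#'
#' @param samples numeric vector (aV).
#' @param fs sampling rate (Hz).
#' @param spec [stimulus_spec()] of the condition (or `NULL`).
#' @param animal animal identifier.
#' @param n_accepted,n_rejected epoch bookkeeping from artifact rejection.
#' @param provenance named list of processing settings applied so far.
#' @return object of class `abr_trace`.
#' @export
abr_trace <- function(samples, fs = ABR_FS, spec = NULL,
                      animal = NA_character_, n_accepted = 1L,
                      n_rejected = 0L, provenance = list()) {
  stopifnot(is.numeric(samples), n_accepted >= 1)
  structure(
    list(samples = as.numeric(samples), fs = fs, spec = spec,
         animal = animal, n_accepted = as.integer(n_accepted),
         n_rejected = as.integer(n_rejected), provenance = provenance),
    class = "abr_trace"
  )
}

#' @export
print.abr_trace <- function(x, ...) {
  cat(sprintf(
    "<abr_trace> %d samples @ %g Hz (%.2f ms), animal = %s, %d/%d epochs kept\n",
    length(x$samples), x$fs, length(x$samples) / x$fs * 1000, x$animal,
    x$n_accepted, x$n_accepted + x$n_rejected))
  if (length(x$provenance)) {
    cat("  processing:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Time axis of a trace (ms)
#' @param trace an `abr_trace`.
#' @export
trace_time_ms <- function(trace) abr_time_ms(length(trace$samples), trace$fs)

## ---- artifact rejection ----------------------------------------------------

#' Reject high-amplitude artifact epochs
#'
#' An epoch is rejected iff its maximum absolute sample *strictly* exceeds
#' the threshold (a sample exactly at threshold is accepted).  The default
#' threshold is 5 times the median absolute deviation of the pooled epoch
#' samples, which sits far above background noise and far below
#' heartbeat-scale artifacts.
#'
#' @param epochs an [abr_epochs()] set.
#' @param threshold rejection threshold in aV; `NULL` for the 5-MAD default.
#' @return list with `accepted` and `rejected` ([abr_epochs()] partitions of
#'   the input), `rejected_idx` (epoch indices) and `threshold` used.
#'   Signals an error of class `abr_all_rejected` when nothing survives.
#' @export
reject_artifacts <- function(epochs, threshold = NULL) {
  stopifnot(inherits(epochs, "abr_epochs"))
  if (is.null(threshold)) {
    threshold <- 5 * stats::mad(epochs$samples, center = 0)
    # degenerate (noise-free) sets have a vanishing MAD: reject nothing
    if (threshold < sqrt(.Machine$double.eps) *
          max(abs(epochs$samples), 1)) {
      threshold <- Inf
    }
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  peak <- apply(abs(epochs$samples), 2, max)
  rejected_idx <- which(peak > threshold)
  if (length(rejected_idx) == ncol(epochs$samples)) {
    stop(structure(
      class = c("abr_all_rejected", "error", "condition"),
      list(message = sprintf(
             "all %d epochs exceed the %.3g aV rejection threshold; condition unusable",
             ncol(epochs$samples), threshold),
           call = sys.call())))
  }
  subset_epochs <- function(idx) {
    abr_epochs(epochs$samples[, idx, drop = FALSE], fs = epochs$fs,
               spec = epochs$spec, animal = epochs$animal,
               artifact_epochs = intersect(epochs$artifact_epochs, idx))
  }
  list(accepted = subset_epochs(setdiff(seq_len(ncol(epochs$samples)),
                                        rejected_idx)),
       rejected = subset_epochs(rejected_idx),
       rejected_idx = rejected_idx,
       threshold = threshold)
}

## ---- averaging -------------------------------------------------------------

#' Average accepted epochs into one trace
#'
#' Pointwise arithmetic mean across repetitions.
#'
#' @param epochs an [abr_epochs()] set (typically the `accepted` partition
#'   from [reject_artifacts()]).
#' @param n_rejected epoch count removed upstream, recorded in the output.
#' @return an [abr_trace()].
#' @export
average_epochs <- function(epochs, n_rejected = 0L) {
  stopifnot(inherits(epochs, "abr_epochs"))
  if (ncol(epochs$samples) < 1L) {
    stop("no epochs to average", call. = FALSE)
  }
  abr_trace(rowMeans(epochs$samples), fs = epochs$fs, spec = epochs$spec,
            animal = epochs$animal,
            n_accepted = ncol(epochs$samples), n_rejected = n_rejected,
            provenance = list(averaged = ncol(epochs$samples)))
}

## ---- filtering -------------------------------------------------------------

design_bandpass <- function(low_hz, high_hz, order, fs) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (low-pass prototype order `order`, so a
#' second-order 50-3000 Hz response at the defaults) applied
#' forward-backward ([signal::filtfilt()]) so that peak latencies are not
#' shifted by filter phase.
#'
#' The 12 ms epoch is shorter than the settling time of the 50 Hz
#' high-pass edge, so two numerical safeguards approximate the
#' infinite-window response: the trace mean is removed first (the DC
#' steady-state response of the band-pass is exactly zero) and the trace
#' is mirror-padded at both ends before the two passes, then trimmed
#' (mirroring keeps the pad at the signal's own level and mean, so no
#' step excites the slow high-pass edge).
#'
#' @param trace an [abr_trace()].
#' @param low_hz,high_hz band edges (Hz).
#' @param order Butterworth prototype order.
#' @return the filtered [abr_trace()] with filter settings appended to its
#'   provenance.
#' @export
bandpass_filter <- function(trace, low_hz = 50, high_hz = 3000, order = 2) {
  stopifnot(inherits(trace, "abr_trace"))
  bf <- design_bandpass(low_hz, high_hz, order, trace$fs)
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  pad <- min(n - 1L, 1024L)
  xp <- c(x[(pad + 1):2],        # mirror, left
          x,
          x[(n - 1):(n - pad)])  # mirror, right
  yp <- signal::filtfilt(bf, xp)
  trace$samples <- yp[(pad + 1):(pad + n)]
  trace$provenance <- c(trace$provenance,
                        list(filter = list(low_hz = low_hz, high_hz = high_hz,
                                           order = order,
                                           phase = "zero (filtfilt)")))
  trace
}

#' Magnitude response of the band-pass as applied
#'
#' Gain of the designed Butterworth band-pass at given frequencies,
#' including the squaring from forward-backward application.  Computed from
#' the transfer-function polynomials, independently of the time-domain
#' filtering path.
#'
#' @param freq_hz frequencies (Hz).
#' @inheritParams bandpass_filter
#' @param fs sampling rate (Hz).
#' @export
bandpass_gain <- function(freq_hz, low_hz = 50, high_hz = 3000, order = 2,
                          fs = ABR_FS) {
  bf <- design_bandpass(low_hz, high_hz, order, fs)
  z <- exp(-1i * 2 * pi * freq_hz / fs)
  h <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^(seq_along(bf$b) - 1))
    den <- sum(bf$a * zz^(seq_along(bf$a) - 1))
    Mod(num / den)
  }, numeric(1))
  h^2  # two passes
}

## ---- baseline --------------------------------------------------------------

#' Zero the baseline of a trace
#'
#' Subtracts the mean over the whole 12 ms window (the window starts at
#' stimulus onset, so there is no pre-stimulus segment to prefer).
#' Idempotent and shift-invariant.
#'
#' @param trace an [abr_trace()].
#' @export
zero_baseline <- function(trace) {
  stopifnot(inherits(trace, "abr_trace"))
  trace$samples <- trace$samples - mean(trace$samples)
  trace$provenance <- c(trace$provenance, list(baseline = "full-window mean"))
  trace
}

## ---- pipeline wrapper ------------------------------------------------------

#' Preprocessing settings
#'
#' @param reject_threshold_av absolute rejection threshold (aV) or `NULL`
#'   for the 5-MAD default.
#' @param filter apply the band-pass? (logical)
#' @param low_hz,high_hz,order band-pass design.
#' @return a named list of class `abr_preprocess_settings`.
#' @export
preprocess_settings <- function(reject_threshold_av = NULL, filter = TRUE,
                                low_hz = 50, high_hz = 3000, order = 2) {
  structure(list(reject_threshold_av = reject_threshold_av, filter = filter,
                 low_hz = low_hz, high_hz = high_hz, order = order),
            class = "abr_preprocess_settings")
}

#' Preprocess an epoch set into one averaged trace
#'
#' Fixed stage order: artifact rejection, averaging, optional zero-phase
#' band-pass, baseline zeroing.  All settings are recorded in the trace's
#' provenance.
#'
#' @param epochs an [abr_epochs()] set.
#' @param settings a [preprocess_settings()] list.
#' @return an [abr_trace()].
#' @export
preprocess_epochs <- function(epochs, settings = preprocess_settings()) {
  rej <- reject_artifacts(epochs, settings$reject_threshold_av)
  trace <- average_epochs(rej$accepted, n_rejected = length(rej$rejected_idx))
  trace$provenance$reject_threshold_av <- rej$threshold
  preprocess_trace(trace, settings)
}

#' Apply the filtering and zeroing stages to an existing trace
#'
#' For traces that are already averages (e.g. synthesized directly with
#' [synth_averaged_trace()]).
#'
#' @inheritParams preprocess_epochs
#' @param trace an [abr_trace()].
#' @export
preprocess_trace <- function(trace, settings = preprocess_settings()) {
  if (isTRUE(settings$filter)) {
    trace <- bandpass_filter(trace, settings$low_hz, settings$high_hz,
                             settings$order)
  }
  zero_baseline(trace)
}
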