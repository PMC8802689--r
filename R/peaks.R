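# Wave I-IV quantification: automatic peak detection with per-wave latency
# windows, trough assignment, peak-to-trough amplitudes, manual overrides
# and the two-ear monaural summary.

WAVE_LABELS <- c("I", "II", "III", "IV")

#' Per-wave search windows
#'
#' Default windows are the generator's wave latencies +/- `half_width_ms`;
#' for recorded data set them from pilot traces.  Overlapping neighbours are
#' truncated at the midpoint between the two wave centres, so windows are
#' always ordered and disjoint.
#'
#' @param centers_ms wave peak latency centres (ms).
#' @param half_width_ms half-width of each window (ms).
#' @return data frame with `wave`, `lo_ms`, `hi_ms`.
#' @export
wave_windows <- function(centers_ms = wave_kernels()$base_latency_ms,
                         half_width_ms = 0.6) {
  stopifnot(length(centers_ms) == 4L, all(diff(centers_ms) > 0),
            half_width_ms > 0)
  lo <- centers_ms - half_width_ms
  hi <- centers_ms + half_width_ms
  mid <- (centers_ms[-4] + centers_ms[-1]) / 2
  hi[-4] <- pmin(hi[-4], mid)
  lo[-1] <- pmax(lo[-1], mid)
  data.frame(wave = WAVE_LABELS, lo_ms = pmax(0, lo), hi_ms = hi)
}

# Topographic prominence of a local maximum at index `i`, restricted to the
# window `idx` (integer index range within the trace).
window_prominence <- function(x, i, lo, hi) {
  left <- x[lo:i]
  right <- x[i:hi]
  # walk outward until a strictly higher sample; base = min over that span
  higher_l <- which(left > x[i])
  lbase <- if (length(higher_l)) min(left[max(higher_l):length(left)])
           else min(left)
  higher_r <- which(right > x[i])
  rbase <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
  x[i] - max(lbase, rbase)
}

local_maxima <- function(x, lo, hi) {
  idx <- lo:hi
  v <- x[idx]
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx[cand]
}

# Noise scale from the pre-wave baseline segment (default first 0.8 ms).
baseline_sd <- function(trace, upto_ms = 0.8) {
  t <- trace_time_ms(trace)
  stats::sd(trace$samples[t < upto_ms])
}

#' Detect ABR waves I-IV
#'
#' For each wave, picks the most prominent local maximum inside its latency
#' window (ties broken toward the earliest latency); candidates below
#' `min_prominence` are ignored and the wave is reported missing, never
#' fabricated.  The trough for each wave is the lowest point between its
#' peak and the next detected wave's peak (for the last detected wave:
#' within `post_window_ms` after the peak), and the amplitude is the
#' peak-to-trough voltage.
#'
#' @param trace an [abr_trace()], normally preprocessed.
#' @param windows per-wave latency windows from [wave_windows()].
#' @param min_prominence minimum peak prominence (aV); `NULL` for the
#'   default of 6 times the pre-wave baseline SD of the trace.
#' @param post_window_ms trough search extent past the final wave's peak.
#' @return object of class `abr_peaks`: a data frame of per-wave rows
#'   (`wave`, `peak_latency_ms`, `peak_value_av`, `trough_latency_ms`,
#'   `trough_value_av`, `amplitude_av`, `source`, `missing`) with the trace
#'   and detection settings attached as attributes.
#' @export
detect_peaks <- function(trace, windows = wave_windows(),
                         min_prominence = NULL, post_window_ms = 1.5) {
  stopifnot(inherits(trace, "abr_trace"))
  t <- trace_time_ms(trace)
  if (max(t) < max(windows$hi_ms)) {
    stop("trace is shorter than the detection windows", call. = FALSE)
  }
  if (is.null(min_prominence)) min_prominence <- 6 * baseline_sd(trace)
  if (is.na(min_prominence) || min_prominence < 0) {
    stop("`min_prominence` must be non-negative", call. = FALSE)
  }
  x <- trace$samples
  peaks <- data.frame(wave = WAVE_LABELS, peak_latency_ms = NA_real_,
                      peak_value_av = NA_real_, trough_latency_ms = NA_real_,
                      trough_value_av = NA_real_, amplitude_av = NA_real_,
                      source = "auto", missing = TRUE)
  peak_idx <- rep(NA_integer_, 4)
  for (w in 1:4) {
    lo <- which(t >= windows$lo_ms[w])[1]
    hi <- max(which(t < windows$hi_ms[w]))
    if (is.na(lo) || lo >= hi) next
    cand <- local_maxima(x, lo, hi)
    if (!length(cand)) next
    prom <- vapply(cand, function(i) window_prominence(x, i, lo, hi),
                   numeric(1))
    keep <- prom >= min_prominence & prom > 0
    if (!any(keep)) next
    cand <- cand[keep]; prom <- prom[keep]
    best <- cand[which(prom == max(prom))][1]  # earliest wins ties
    peak_idx[w] <- best
    peaks$peak_latency_ms[w] <- t[best]
    peaks$peak_value_av[w] <- x[best]
    peaks$missing[w] <- FALSE
  }
  peaks <- assign_troughs(peaks, peak_idx, x, t, trace$fs, post_window_ms)
  structure(peaks,
            class = c("abr_peaks", "data.frame"),
            trace = trace,
            settings = list(windows = windows,
                            min_prominence = min_prominence,
                            post_window_ms = post_window_ms))
}

# Recompute troughs/amplitudes for all detected peaks ("the trough was the
# lowest point for that wave": minimum between this peak and the next
# detected wave's peak; for the last wave, within post_window_ms).
assign_troughs <- function(peaks, peak_idx, x, t, fs, post_window_ms) {
  n <- length(x)
  detected <- which(!is.na(peak_idx))
  for (j in seq_along(detected)) {
    w <- detected[j]
    ip <- peak_idx[w]
    stop_at <- if (j < length(detected)) {
      peak_idx[detected[j + 1]]
    } else {
      min(n, ip + round(post_window_ms / 1000 * fs))
    }
    if (stop_at <= ip + 1L) stop_at <- min(n, ip + 2L)
    seg <- (ip + 1L):stop_at
    it <- seg[which.min(x[seg])]
    peaks$trough_latency_ms[w] <- t[it]
    peaks$trough_value_av[w] <- x[it]
    peaks$amplitude_av[w] <- x[ip] - x[it]
  }
  peaks
}

#' @export
print.abr_peaks <- function(x, ...) {
  cat("<abr_peaks>\n")
  df <- as.data.frame(x)
  df$peak_latency_ms <- round(df$peak_latency_ms, 4)
  df$amplitude_av <- round(df$amplitude_av, 4)
  print(df[, c("wave", "peak_latency_ms", "amplitude_av", "source",
               "missing")], row.names = FALSE)
  invisible(x)
}

#' Apply manual peak corrections
#'
#' Mirrors visual-confirmation workflows: a wave's peak can be moved to a
#' stated latency (`set`) or the wave removed (`clear`).  Edited waves are
#' marked `source = "manual"`; troughs and amplitudes of all detected waves
#' are recomputed with the same trough rule so the invariants (ordering,
#' non-negative amplitude) still hold.  An edit that breaks the strict
#' latency ordering of detected waves is rejected.
#'
#' @param peaks an `abr_peaks` object from [detect_peaks()].
#' @param set named numeric vector of peak latencies (ms) keyed by wave
#'   label, e.g. `c(IV = 4.35)`.
#' @param clear character vector of wave labels to mark missing.
#' @return the edited `abr_peaks` object.
#' @export
apply_manual_override <- function(peaks, set = NULL, clear = NULL) {
  stopifnot(inherits(peaks, "abr_peaks"))
  trace <- attr(peaks, "trace")
  settings <- attr(peaks, "settings")
  t <- trace_time_ms(trace)
  x <- trace$samples
  out <- as.data.frame(peaks)
  peak_idx <- vapply(out$peak_latency_ms, function(l) {
    if (is.na(l)) NA_integer_ else which.min(abs(t - l))
  }, integer(1))

  for (w in clear) {
    k <- match(w, WAVE_LABELS)
    if (is.na(k)) stop("unknown wave label: ", w, call. = FALSE)
    out[k, c("peak_latency_ms", "peak_value_av", "trough_latency_ms",
             "trough_value_av", "amplitude_av")] <- NA_real_
    out$missing[k] <- TRUE
    out$source[k] <- "manual"
    peak_idx[k] <- NA_integer_
  }
  if (!is.null(set)) {
    if (is.null(names(set)) || !all(names(set) %in% WAVE_LABELS)) {
      stop("`set` must be named with wave labels I-IV", call. = FALSE)
    }
    for (w in names(set)) {
      k <- match(w, WAVE_LABELS)
      lat <- set[[w]]
      if (lat < 0 || lat > max(t)) {
        stop("override latency for wave ", w, " lies outside the trace",
             call. = FALSE)
      }
      i <- which.min(abs(t - lat))
      peak_idx[k] <- i
      out$peak_latency_ms[k] <- t[i]
      out$peak_value_av[k] <- x[i]
      out$missing[k] <- FALSE
      out$source[k] <- "manual"
    }
  }
  lat_ok <- out$peak_latency_ms[!out$missing]
  if (any(diff(lat_ok) <= 0)) {
    stop("override rejected: wave peak latencies must remain strictly ",
         "increasing in wave order", call. = FALSE)
  }
  out$trough_latency_ms <- NA_real_
  out$trough_value_av <- NA_real_
  out$amplitude_av <- NA_real_
  out <- assign_troughs(out, peak_idx, x, t, trace$fs,
                        settings$post_window_ms)
  structure(out, class = c("abr_peaks", "data.frame"),
            trace = trace, settings = settings)
}

#' Two-ear monaural summary
#'
#' Per wave, the arithmetic mean of the left- and right-ear amplitude and
#' latency.  A wave missing in one ear falls back to the other ear's value
#' and is flagged; a wave missing in both ears stays missing.
#'
#' @param left,right `abr_peaks` objects for the two ears at the same
#'   stimulus level.
#' @return data frame with `wave`, `amplitude_av`, `latency_ms`, `n_ears`
#'   and `flagged` (single-ear fallback).
#' @export
monaural_summary <- function(left, right) {
  stopifnot(inherits(left, "abr_peaks"), inherits(right, "abr_peaks"))
  lspec <- attr(left, "trace")$spec
  rspec <- attr(right, "trace")$spec
  if (!is.null(lspec) && !is.null(rspec) && lspec$level != rspec$level) {
    stop("the two ears must be measured at the same level", call. = FALSE)
  }
  out <- data.frame(wave = WAVE_LABELS, amplitude_av = NA_real_,
                    latency_ms = NA_real_, n_ears = 0L, flagged = FALSE)
  for (k in 1:4) {
    amp <- c(left$amplitude_av[k], right$amplitude_av[k])
    lat <- c(left$peak_latency_ms[k], right$peak_latency_ms[k])
    ok <- !is.na(amp)
    out$n_ears[k] <- sum(ok)
    if (!any(ok)) next
    out$amplitude_av[k] <- mean(amp[ok])
    out$latency_ms[k] <- mean(lat[ok])
    out$flagged[k] <- sum(ok) == 1L
  }
  out
}
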