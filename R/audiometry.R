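# Hearing-threshold estimation: an algorithmic surrogate for visual
# response detection, level-series threshold search with monotone
# enforcement, and audiogram assembly over the 8-frequency grid.

#' Decide whether a trace contains an evoked response
#'
#' Algorithmic stand-in for human visual detection.  Two detectors share
#' the interface:
#' \describe{
#'   \item{`"rms"`}{response present iff the RMS of the trace inside the
#'     response window strictly exceeds `criterion_multiple * noise_floor`.}
#'   \item{`"template"`}{matched filter: the trace (window) is projected on
#'     the unit-normalized suprathreshold `template` waveform; response
#'     present iff the projection strictly exceeds
#'     `criterion_multiple * noise_floor`.  Far more sensitive near
#'     threshold because noise is integrated coherently.}
#' }
#'
#' @param trace an [abr_trace()].
#' @param noise_floor noise scale (aV): the RMS of a subthreshold trace of
#'   the same series inside the response window.
#' @param criterion_multiple detection criterion (default 2).
#' @param window_ms response window (ms), covering waves I-IV.
#' @param method `"rms"` or `"template"`.
#' @param template an [abr_trace()] of a clearly suprathreshold condition
#'   from the same series (required for `method = "template"`).
#' @return logical.
#' @export
detect_response <- function(trace, noise_floor, criterion_multiple = 2,
                            window_ms = c(1, 6),
                            method = c("rms", "template"),
                            template = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "abr_trace"))
  if (!is.numeric(noise_floor) || noise_floor < 0) {
    stop("`noise_floor` must be non-negative", call. = FALSE)
  }
  t <- trace_time_ms(trace)
  sel <- t >= window_ms[1] & t < window_ms[2]
  if (!any(sel)) stop("degenerate response window", call. = FALSE)
  x <- trace$samples[sel]
  statistic <- switch(method,
    rms = sqrt(mean(x^2)),
    template = {
      if (is.null(template)) {
        stop("`template` is required for the matched-filter detector",
             call. = FALSE)
      }
      u <- template$samples[sel]
      nu <- sqrt(sum(u^2))
      if (nu == 0) 0 else sum(x * u) / nu
    })
  statistic > criterion_multiple * noise_floor
}

#' Estimate hearing threshold from a descending level series
#'
#' The threshold is the lowest tested level at which a response is detected
#' *and* detection also succeeds at every higher tested level (monotone
#' enforcement, smoothing isolated detector flips the way a human rater
#' implicitly would).  If detection fails at the highest level the series is
#' reported as no-response (`NA`).  Thresholds are reported as tested
#' levels, never interpolated.
#'
#' @param traces list of [abr_trace()]s, one per level, in the same order as
#'   `levels`.
#' @param levels strictly descending dB SPL levels (steps of 5-10 dB).
#' @param criterion_multiple,window_ms,method passed to [detect_response()].
#' @param noise_floor noise scale; `NULL` to estimate it as the RMS of the
#'   lowest-level (subthreshold) trace of the series inside the window.
#' @param template template trace for the matched-filter detector; `NULL`
#'   to use the highest-level trace of the series.
#' @return list of class `abr_threshold`: `threshold_db` (`NA` =
#'   no-response), `detected` per level, `levels`, `noise_floor`, settings.
#' @export
estimate_threshold <- function(traces, levels, criterion_multiple = 2,
                               window_ms = c(1, 6),
                               method = c("rms", "template"),
                               noise_floor = NULL, template = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(traces), length(traces) == length(levels),
            length(levels) >= 2)
  if (any(diff(levels) >= 0)) {
    stop("`levels` must be strictly descending", call. = FALSE)
  }
  step <- unique(abs(diff(levels)))
  if (any(step < 5 - 1e-9 | step > 10 + 1e-9)) {
    stop("level steps must lie in [5, 10] dB SPL", call. = FALSE)
  }
  if (is.null(noise_floor)) {
    low <- traces[[length(traces)]]
    t <- trace_time_ms(low)
    sel <- t >= window_ms[1] & t < window_ms[2]
    noise_floor <- sqrt(mean(low$samples[sel]^2))
  }
  if (method == "template" && is.null(template)) template <- traces[[1]]
  detected <- vapply(traces, detect_response, logical(1),
                     noise_floor = noise_floor,
                     criterion_multiple = criterion_multiple,
                     window_ms = window_ms, method = method,
                     template = template)
  run <- cumprod(detected) == 1  # detected at this level and all above
  threshold <- if (any(run)) levels[max(which(run))] else NA_real_
  structure(list(threshold_db = threshold, detected = detected,
                 levels = levels, noise_floor = noise_floor,
                 settings = list(criterion_multiple = criterion_multiple,
                                 window_ms = window_ms, method = method)),
            class = "abr_threshold")
}

#' @export
print.abr_threshold <- function(x, ...) {
  cat(sprintf("<abr_threshold> %s (levels %s)\n",
              if (is.na(x$threshold_db)) "no response"
              else paste0(x$threshold_db, " dB SPL"),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Assemble an audiogram from per-frequency level series
#'
#' @param series named list keyed by frequency (kHz as character or
#'   numeric names); each element a list with `traces` and `levels` as for
#'   [estimate_threshold()], or an already-computed `abr_threshold`.
#' @param ... further arguments passed to [estimate_threshold()].
#' @return object of class `abr_audiogram`: data frame with
#'   `frequency_khz`, `threshold_db` (`NA` = no response) and
#'   `no_response`, plus the criterion settings as an attribute.
#' @export
build_audiogram <- function(series, ...) {
  freqs <- as.numeric(names(series))
  if (any(is.na(freqs)) ||
      !all(vapply(freqs, function(f)
        any(abs(f - tone_frequencies_khz()) < 1e-9), logical(1)))) {
    stop("series names must be audiogram frequencies (kHz)", call. = FALSE)
  }
  if (anyDuplicated(freqs)) {
    stop("duplicate frequency entries", call. = FALSE)
  }
  ord <- order(freqs)
  thresholds <- lapply(series, function(s) {
    if (inherits(s, "abr_threshold")) s
    else estimate_threshold(s$traces, s$levels, ...)
  })
  out <- data.frame(
    frequency_khz = freqs[ord],
    threshold_db = vapply(thresholds[ord], `[[`, numeric(1), "threshold_db")
  )
  out$no_response <- is.na(out$threshold_db)
  structure(out, class = c("abr_audiogram", "data.frame"),
            settings = attr(thresholds[[1]], "settings"))
}

#' @export
print.abr_audiogram <- function(x, ...) {
  cat("<abr_audiogram>\n")
  df <- as.data.frame(x)
  df$threshold_db <- ifelse(df$no_response, "no response",
                            as.character(df$threshold_db))
  print(df[, c("frequency_khz", "threshold_db")], row.names = FALSE)
  invisible(x)
}
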