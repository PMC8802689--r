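# Binaural interaction component (BIC): subtraction of the summed monaural
# traces from the binaural trace, DN1 localisation anchored to wave IV of
# the summed response, and amplitude/latency-versus-ITD series.

#' Compute the binaural interaction component
#'
#' `BIC = binaural - (left + right)`, pointwise.  All three traces must
#' share length, sampling rate and animal and should have been preprocessed
#' identically; the left/right traces are the monaural components of the
#' same ITD condition (recorded with the matching per-ear stimulus delays).
#'
#' @param left,right,binaural [abr_trace()]s.
#' @return object of class `abr_bic`: list with `samples`, `fs`, `itd_ms`,
#'   and the three parent traces.
#' @export
compute_bic <- function(left, right, binaural) {
  for (tr in list(left, right, binaural)) stopifnot(inherits(tr, "abr_trace"))
  if (length(left$samples) != length(right$samples) ||
      length(left$samples) != length(binaural$samples)) {
    stop("parent traces must have equal length", call. = FALSE)
  }
  if (left$fs != right$fs || left$fs != binaural$fs) {
    stop("parent traces must share the sampling rate", call. = FALSE)
  }
  animals <- unique(stats::na.omit(c(left$animal, right$animal,
                                     binaural$animal)))
  if (length(animals) > 1) {
    stop("parent traces come from different animals", call. = FALSE)
  }
  itd <- if (!is.null(binaural$spec)) binaural$spec$itd_ms else NULL
  structure(
    list(samples = binaural$samples - (left$samples + right$samples),
         fs = binaural$fs,
         itd_ms = if (is.null(itd)) NA_real_ else itd,
         left = left, right = right, binaural = binaural),
    class = "abr_bic"
  )
}

#' @export
print.abr_bic <- function(x, ...) {
  cat(sprintf("<abr_bic> %d samples @ %g Hz, ITD %s ms\n",
              length(x$samples), x$fs,
              ifelse(is.na(x$itd_ms), "?", format(x$itd_ms))))
  invisible(x)
}

#' Summed (left + right) monaural trace
#'
#' The summed ABR used both as the DN1 anchor reference and for display.
#' @param left,right [abr_trace()]s.
#' @export
summed_trace <- function(left, right) {
  stopifnot(length(left$samples) == length(right$samples))
  abr_trace(left$samples + right$samples, fs = left$fs, spec = left$spec,
            animal = left$animal,
            n_accepted = left$n_accepted,
            provenance = list(summed = "left + right"))
}

#' Locate the DN1 deflection of a BIC trace
#'
#' DN1 is the prominent negative wave of the BIC aligned with wave IV.  The
#' search window is `anchor_latency_ms +/- (half_window_ms + |itd|/2)`
#' where the anchor is the wave IV peak of the summed trace; the widening
#' tracks lateralized shifts.  The DN1 latency is the argmin of the BIC
#' inside the window; the amplitude is the magnitude of that minimum
#' relative to the zero baseline.  The deflection is reported absent when
#' the minimum is not negative or its magnitude does not exceed the noise
#' floor (3 times the RMS of the BIC outside the search window, plus a tiny
#' numerical guard).
#'
#' @param bic an [compute_bic()] result.
#' @param anchor_latency_ms wave IV peak latency of the summed trace (ms);
#'   `NA` when wave IV was not detected.
#' @param half_window_ms half-width of the search window before ITD
#'   widening (ms).
#' @param noise_floor_multiple absence criterion multiplier.
#' @return object of class `abr_dn1`: list with `present`, `latency_ms`,
#'   `amplitude_av` (non-negative magnitude), `value_av` (signed minimum),
#'   `itd_ms`, `window_ms` and `reason` when absent.
#' @export
find_dn1 <- function(bic, anchor_latency_ms, half_window_ms = 1.5,
                     noise_floor_multiple = 3) {
  stopifnot(inherits(bic, "abr_bic"))
  absent <- function(reason) {
    structure(list(present = FALSE, latency_ms = NA_real_,
                   amplitude_av = NA_real_, value_av = NA_real_,
                   itd_ms = bic$itd_ms, window_ms = c(NA_real_, NA_real_),
                   reason = reason),
              class = "abr_dn1")
  }
  if (is.na(anchor_latency_ms)) {
    return(absent("no wave IV anchor on the summed trace"))
  }
  t <- abr_time_ms(length(bic$samples), bic$fs)
  half <- half_window_ms +
    (if (is.na(bic$itd_ms)) 0 else abs(bic$itd_ms) / 2)
  win <- c(anchor_latency_ms - half, anchor_latency_ms + half)
  sel <- t >= win[1] & t <= win[2]
  if (!any(sel)) return(absent("search window outside the trace"))
  x <- bic$samples
  i_min <- which(sel)[which.min(x[sel])]
  value <- x[i_min]
  floor <- noise_floor_multiple * sqrt(mean(x[!sel]^2)) + 1e-12
  if (value >= 0 || abs(value) <= floor) {
    out <- absent("no negative deflection above the noise floor")
    out$window_ms <- win
    return(out)
  }
  structure(list(present = TRUE, latency_ms = t[i_min],
                 amplitude_av = abs(value), value_av = value,
                 itd_ms = bic$itd_ms, window_ms = win, reason = NA_character_),
            class = "abr_dn1")
}

#' @export
print.abr_dn1 <- function(x, ...) {
  if (x$present) {
    cat(sprintf("<abr_dn1> latency %.4f ms, amplitude %.4f aV (ITD %s ms)\n",
                x$latency_ms, x$amplitude_av, format(x$itd_ms)))
  } else {
    cat(sprintf("<abr_dn1> absent: %s\n", x$reason))
  }
  invisible(x)
}

#' DN1 measurements across an ITD series
#'
#' Runs [compute_bic()] and [find_dn1()] for each ITD triplet.  The wave IV
#' anchor is taken from peak detection on the summed trace of each
#' condition.
#'
#' At nonzero ITD the summed trace is lateralized: each ear's contribution
#' is shifted by `itd/2`, so the wave IV search window is widened by
#' `|itd|/2` on both sides before anchoring, and the prominence floor for
#' the anchor detection defaults to 6 times the RMS of the quiet tail of
#' the summed trace (the pre-wave baseline is contaminated by the shifted
#' wave I at large ITDs).
#'
#' @param triplets list of lists, each with elements `left`, `right`,
#'   `binaural` ([abr_trace()]s) for one ITD; ITDs are read from the
#'   binaural specs and must be unique grid values.
#' @param windows,min_prominence passed to [detect_peaks()] for the summed
#'   trace (`min_prominence = NULL` uses the tail-RMS default above).
#' @param half_window_ms,noise_floor_multiple passed to [find_dn1()].
#' @return object of class `abr_bic_series`: data frame with one row per
#'   ITD (`itd_ms`, `present`, `latency_ms`, `amplitude_av`, `reason`).
#' @export
bic_itd_series <- function(triplets, windows = wave_windows(),
                           min_prominence = NULL, half_window_ms = 1.5,
                           noise_floor_multiple = 3) {
  itds <- vapply(triplets, function(tr) {
    itd <- tr$binaural$spec$itd_ms
    if (is.null(itd)) NA_real_ else itd
  }, numeric(1))
  if (any(is.na(itds))) stop("every binaural trace needs an ITD",
                             call. = FALSE)
  if (anyDuplicated(itds)) stop("duplicate ITD in series", call. = FALSE)
  rows <- lapply(seq_along(triplets), function(k) {
    tr <- triplets[[k]]
    summed <- summed_trace(tr$left, tr$right)
    wins <- windows
    wins$lo_ms[4] <- wins$lo_ms[4] - abs(itds[k]) / 2
    wins$hi_ms[4] <- wins$hi_ms[4] + abs(itds[k]) / 2
    prom <- min_prominence
    if (is.null(prom)) {
      t <- trace_time_ms(summed)
      prom <- 6 * sqrt(mean(summed$samples[t >= 8]^2))
    }
    pk <- detect_peaks(summed, windows = wins, min_prominence = prom)
    anchor <- pk$peak_latency_ms[pk$wave == "IV"]
    bic <- compute_bic(tr$left, tr$right, tr$binaural)
    dn1 <- find_dn1(bic, anchor, half_window_ms = half_window_ms,
                    noise_floor_multiple = noise_floor_multiple)
    data.frame(itd_ms = itds[k], present = dn1$present,
               latency_ms = dn1$latency_ms,
               amplitude_av = dn1$amplitude_av,
               reason = ifelse(is.na(dn1$reason), "", dn1$reason))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$itd_ms), ]
  rownames(out) <- NULL
  structure(out, class = c("abr_bic_series", "data.frame"))
}

#' @export
print.abr_bic_series <- function(x, ...) {
  cat("<abr_bic_series>\n")
  print(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}
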