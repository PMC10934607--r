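#' Heart-sound template
#'
#' A signal excerpt capturing the typical morphology of S1, S2, or a whole
#' S1-S2 pair. The offset of the template's absolute maximum is recorded so
#' that the similarity trace can be re-aligned: an NCC peak is then stamped
#' with the time at which the template's maximum lands on the signal, which
#' makes event times directly comparable across templates.
#'
#' @param samples Numeric vector of template samples (length >= 3, not all
#'   equal).
#' @param fs Sampling rate in Hz; must match the signal the template is
#'   applied to.
#' @param label One of `"S1"`, `"S2"`, `"S1S2"`.
#' @param peak_offset 0-based sample index of the template's absolute
#'   maximum. Computed from `samples` when omitted (see `use_abs`).
#' @param source_span Optional `(start_s, end_s)` span in the source signal.
#' @param use_abs If `TRUE`, the absolute maximum is taken on `|samples|`;
#'   by default the maximum of the signed samples is used (heart-sound
#'   figures mark positive peaks).
#' @return An object of class `hs_template`.
#' @export
hs_template <- function(samples, fs, label = c("S1", "S2", "S1S2"),
                        peak_offset = NULL, source_span = NULL,
                        use_abs = FALSE) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) < 3L)
    stop("a template needs at least 3 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("template samples must be finite", call. = FALSE)
  if (max(samples) == min(samples))
    stop("invalid template: all samples equal (zero variance)",
         call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (is.null(peak_offset))
    peak_offset <- (if (use_abs) which.max(abs(samples))
                    else which.max(samples)) - 1L
  peak_offset <- as.integer(peak_offset)
  if (peak_offset < 0L || peak_offset >= length(samples))
    stop("`peak_offset` out of range", call. = FALSE)
  structure(list(samples = samples, fs = fs, label = label,
                 peak_offset = peak_offset, source_span = source_span),
            class = "hs_template")
}

#' @export
print.hs_template <- function(x, ...) {
  cat(sprintf("<hs_template> %s, %d samples @ %g Hz, peak at %.3f s",
              x$label, length(x$samples), x$fs, x$peak_offset / x$fs))
  if (!is.null(x$source_span))
    cat(sprintf(", from [%.3f, %.3f] s", x$source_span[1], x$source_span[2]))
  cat("\n")
  invisible(x)
}

#' Extract a template from a signal span
#'
#' Copies the `[start_s, end_s)` span of the heart-sound signal into a
#' template. Good manual selections enclose all the oscillations of the
#' sound plus short tracts before and after it (for an S1-S2 template: both
#' sounds and the interval in between).
#'
#' @param signal A [uniform_signal()] (the heart-sound component).
#' @param start_s,end_s Span boundaries in seconds (half-open), within the
#'   signal and at least 3 samples long.
#' @param label One of `"S1"`, `"S2"`, `"S1S2"`.
#' @param use_abs Passed to [hs_template()].
#' @return An [hs_template()].
#' @export
extract_template <- function(signal, start_s, end_s,
                             label = c("S1", "S2", "S1S2"),
                             use_abs = FALSE) {
  stopifnot(inherits(signal, "uniform_signal"))
  label <- match.arg(label)
  t_end <- signal$t0 + length(signal$samples) / signal$fs
  if (!(start_s >= signal$t0 && start_s < end_s && end_s <= t_end))
    stop("template span must satisfy t0 <= start_s < end_s <= signal end",
         call. = FALSE)
  i0 <- floor((start_s - signal$t0) * signal$fs) + 1L
  i1 <- min(length(signal$samples), ceiling((end_s - signal$t0) * signal$fs))
  if (i1 - i0 + 1L < 3L)
    stop("template span must cover at least 3 samples", call. = FALSE)
  hs_template(signal$samples[i0:i1], fs = signal$fs, label = label,
              source_span = c(start_s, end_s), use_abs = use_abs)
}

#' Normalized cross-correlation of a signal with a template
#'
#' Slides the template along the signal and computes, at each window
#' position, the zero-mean normalized cross-correlation
#' \deqn{v_k = \frac{\sum_i (x_{k+i} - \bar x_k)(t_i - \bar t)}
#'   {\sqrt{\sum_i (x_{k+i} - \bar x_k)^2 \sum_i (t_i - \bar t)^2}},}
#' a similarity measure in \[-1, 1\] that is invariant to amplitude scaling
#' and offset of the signal chunk. Windows with zero variance map to 0
#' (neutral similarity); because the measure is amplitude-invariant, the
#' same neutralization is applied to near-silent windows — those whose
#' centred RMS is below `flat_tol` times the loudest window's — so that
#' sensor noise in otherwise flat stretches cannot produce spurious
#' similarity peaks. The trace's time axis is re-aligned by the
#' template's `peak_offset`, so a value at time \eqn{\tau} measures the
#' similarity of the window whose template-maximum sample lands at
#' \eqn{\tau}.
#'
#' The sliding sums are computed via FFT cross-correlation and cumulative
#' sums, so the cost is `O(N log N)` rather than `O(N M)`.
#'
#' @param signal A [uniform_signal()].
#' @param template An [hs_template()] with the same sampling rate and not
#'   longer than the signal.
#' @param zero_mean If `FALSE`, the non-centred variant
#'   \eqn{\sum x t / \sqrt{\sum x^2 \sum t^2}} is computed instead.
#' @param flat_tol Relative RMS floor for the flat-window rule (default
#'   0.03). Set to 0 for the exact textbook NCC on every window.
#' @return An object of class `ncc_trace` with fields `values` (length
#'   `length(signal) - length(template) + 1`), `fs`, `t0` (time of the
#'   first value, already re-aligned), `label`.
#' @export
ncc <- function(signal, template, zero_mean = TRUE, flat_tol = 0.03) {
  stopifnot(inherits(signal, "uniform_signal"),
            inherits(template, "hs_template"))
  if (signal$fs != template$fs)
    stop("signal and template sampling rates differ", call. = FALSE)
  x <- signal$samples
  tpl <- template$samples
  n <- length(x); m <- length(tpl)
  if (m > n) stop("template longer than signal", call. = FALSE)
  if (zero_mean) {
    tc <- tpl - mean(tpl)
  } else {
    tc <- tpl
  }
  sst <- sum(tc^2)
  if (sst <= 0)
    stop("invalid template: zero variance", call. = FALSE)
  # sliding dot product x_window . tc: FFT cross-correlation, zero-padded
  # to a 2-3-5-smooth length so the transform stays O(N log N) for any N
  len <- stats::nextn(n + m - 1L, c(2, 3, 5))
  xf <- stats::fft(c(x, numeric(len - n)))
  tf <- stats::fft(c(tc, numeric(len - m)))
  cc <- Re(stats::fft(xf * Conj(tf), inverse = TRUE)) / len
  num <- cc[1:(n - m + 1)]
  cs2 <- c(0, cumsum(x^2))
  ss_raw <- cs2[(m + 1):(n + 1)] - cs2[1:(n - m + 1)]
  if (zero_mean) {
    cs1 <- c(0, cumsum(x))
    s <- cs1[(m + 1):(n + 1)] - cs1[1:(n - m + 1)]
    ssx <- ss_raw - s^2 / m
  } else {
    ssx <- ss_raw
  }
  ssx <- pmax(ssx, 0)
  zero_var <- ssx <= 1e-12 * ss_raw | ss_raw == 0
  if (flat_tol > 0) zero_var <- zero_var | ssx < flat_tol^2 * max(ssx)
  denom <- sqrt(ssx * sst)
  v <- numeric(n - m + 1)
  ok <- !zero_var
  v[ok] <- num[ok] / denom[ok]
  v <- pmin(1, pmax(-1, v))
  structure(list(values = v, fs = signal$fs,
                 t0 = signal$t0 + template$peak_offset / signal$fs,
                 label = template$label),
            class = "ncc_trace")
}

#' @export
print.ncc_trace <- function(x, ...) {
  cat(sprintf("<ncc_trace> %s, %d values @ %g Hz, max %.3f\n",
              x$label, length(x$values), x$fs, max(x$values)))
  invisible(x)
}

#' Localize events as local maxima of an NCC trace
#'
#' Finds strict local maxima of the similarity trace at or above
#' `min_height`, then greedily keeps the highest peaks while suppressing any
#' peak closer than `min_distance_s` to an already accepted one (equal
#' heights: the earlier peak wins). Each retained peak is an event; its time
#' is in the signal's clock thanks to the trace's re-alignment.
#'
#' @param trace An `ncc_trace` from [ncc()].
#' @param min_height Minimum similarity for a peak to count (default 0.5).
#' @param min_distance_s Minimum separation between events in seconds
#'   (default 0.3, a refractory bound adequate up to 200 bpm).
#' @return An [event_series()] labelled like the template.
#' @export
find_events <- function(trace, min_height = 0.5, min_distance_s = 0.3) {
  stopifnot(inherits(trace, "ncc_trace"))
  v <- trace$values
  n <- length(v)
  if (n < 3) return(event_series(numeric(0), trace$label))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  idx <- idx[v[idx] >= min_height]
  if (!length(idx)) return(event_series(numeric(0), trace$label))
  # greedy non-maximum suppression: higher value first, earlier index breaks
  # ties
  ord <- idx[order(-v[idx], idx)]
  min_gap <- min_distance_s * trace$fs
  accepted <- integer(0)
  for (i in ord)
    if (!length(accepted) || all(abs(accepted - i) >= min_gap))
      accepted <- c(accepted, i)
  accepted <- sort(accepted)
  event_series(trace$t0 + (accepted - 1) / trace$fs, trace$label)
}

# Short-time energy envelope: squared signal smoothed by a centred moving
# average of width win_s.
ste_envelope <- function(x, fs, win_s = 0.05) {
  w <- max(3L, round(win_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2, circular = FALSE))
}

#' Automatically select a template from a heart-sound signal
#'
#' Convenience alternative to manual selection: locates the globally
#' strongest short-time-energy burst and cuts a label-dependent window
#' around it. For `"S2"` the burst searched is the strongest one 0.2-0.5 s
#' after the global (S1) burst; for `"S1S2"` the window runs from just
#' before the S1 burst to just after the following S2 burst.
#'
#' @param signal A [uniform_signal()] (heart-sound component), at least 5 s
#'   long.
#' @param label One of `"S1"`, `"S2"`, `"S1S2"`.
#' @param approx_rate_bpm Optional approximate heart rate (unused by the
#'   default burst rule; reserved for rate-adaptive window widths).
#' @return An [hs_template()].
#' @export
auto_select_template <- function(signal, label = c("S1", "S2", "S1S2"),
                                 approx_rate_bpm = NULL) {
  stopifnot(inherits(signal, "uniform_signal"))
  label <- match.arg(label)
  if (signal_duration(signal) < 5)
    stop("need at least 5 s of signal for automatic selection",
         call. = FALSE)
  env <- ste_envelope(signal$samples, signal$fs)
  env[is.na(env)] <- 0
  if (max(env) <= 0)
    stop("no energy burst found in the signal", call. = FALSE)
  tt <- signal_times(signal)
  # keep the global burst away from the edges so the window fits
  inner <- which(tt > tt[1] + 0.5 & tt < tt[length(tt)] - 1.0)
  t_s1 <- tt[inner[which.max(env[inner])]]
  s2_burst <- function() {
    win <- which(tt >= t_s1 + 0.2 & tt <= t_s1 + 0.5)
    if (!length(win) || max(env[win]) <= 0)
      stop("no S2 burst found after the S1 burst", call. = FALSE)
    tt[win[which.max(env[win])]]
  }
  span <- switch(label,
    S1 = c(t_s1 - 0.06, t_s1 + 0.06),
    S2 = { t2 <- s2_burst(); c(t2 - 0.05, t2 + 0.05) },
    S1S2 = { t2 <- s2_burst(); c(t_s1 - 0.075, t2 + 0.075) })
  span[1] <- max(span[1], signal$t0)
  span[2] <- min(span[2], signal$t0 + length(signal$samples) / signal$fs)
  extract_template(signal, span[1], span[2], label = label)
}

#' Detect heart sounds in a signal with a template
#'
#' One-call wrapper: [ncc()] followed by [find_events()].
#'
#' @inheritParams ncc
#' @inheritParams find_events
#' @return An [event_series()].
#' @export
detect_events <- function(signal, template, min_height = 0.5,
                          min_distance_s = 0.3, zero_mean = TRUE,
                          flat_tol = 0.03) {
  find_events(ncc(signal, template, zero_mean = zero_mean,
                  flat_tol = flat_tol),
              min_height = min_height, min_distance_s = min_distance_s)
}
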