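#' Pair detected events with reference beats
#'
#' Detected heart-sound events lag the ECG R-peaks by a roughly constant
#' electromechanical delay, so each detected time `d` is matched to the
#' reference beat minimizing `|d - (r + expected_lag_s)|`. Assignment is
#' one-to-one and greedy by ascending residual; a pairing is accepted only
#' if its residual is at most `tol_s`. Unmatched reference beats are missed
#' events (FN), unmatched detections are false events (FP).
#'
#' @param detected,reference [event_series()] objects (strictly increasing
#'   times). `reference` must be non-empty.
#' @param expected_lag_s Expected detected-minus-reference lag in seconds.
#'   When `NULL` (default) it is self-calibrated as the median of
#'   `d_nearest - r` over all reference beats.
#' @param tol_s Acceptance tolerance on the residual in seconds
#'   (default 0.15).
#' @return An object of class `beat_match` with fields `assignments`
#'   (per reference beat, the matched detected index or `NA`),
#'   `unmatched_detections`, `tp`, `fp`, `fn`, `expected_lag_s`.
#' @export
match_events <- function(detected, reference, expected_lag_s = NULL,
                         tol_s = 0.15) {
  stopifnot(inherits(detected, "event_series"),
            inherits(reference, "event_series"))
  d <- detected$times
  r <- reference$times
  if (!length(r)) stop("empty reference series", call. = FALSE)
  if (is.null(expected_lag_s)) {
    if (length(d)) {
      nearest <- vapply(r, function(ri) d[which.min(abs(d - ri))] - ri,
                        numeric(1))
      expected_lag_s <- stats::median(nearest)
    } else {
      expected_lag_s <- 0
    }
  }
  assignments <- rep(NA_integer_, length(r))
  if (length(d)) {
    # candidate pairs within tolerance, greedily accepted by residual
    cand <- do.call(rbind, lapply(seq_along(d), function(j) {
      res <- abs(d[j] - (r + expected_lag_s))
      keep <- which(res <= tol_s)
      if (!length(keep)) return(NULL)
      cbind(det = j, ref = keep, res = res[keep])
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand[, "res"]), , drop = FALSE]
      det_used <- logical(length(d))
      for (i in seq_len(nrow(cand))) {
        dj <- cand[i, "det"]; rk <- cand[i, "ref"]
        if (!det_used[dj] && is.na(assignments[rk])) {
          assignments[rk] <- dj
          det_used[dj] <- TRUE
        }
      }
    }
  }
  tp <- sum(!is.na(assignments))
  structure(list(assignments = assignments,
                 unmatched_detections =
                   setdiff(seq_along(d), assignments[!is.na(assignments)]),
                 tp = tp, fp = length(d) - tp, fn = length(r) - tp,
                 expected_lag_s = expected_lag_s,
                 n_detected = length(d), n_reference = length(r)),
            class = "beat_match")
}

#' @export
print.beat_match <- function(x, ...) {
  cat(sprintf("<beat_match> TP %d, FP %d, FN %d (lag %.1f ms)\n",
              x$tp, x$fp, x$fn, 1000 * x$expected_lag_s))
  invisible(x)
}

#' Recognition statistics of a beat match
#'
#' Sensitivity `TP / (TP + FN) * 100` and positive predictive value
#' `TP / (TP + FP) * 100`. Values are exact; round only for presentation.
#'
#' @param match A `beat_match` from [match_events()], or a list/vector with
#'   elements `tp`, `fp`, `fn`.
#' @return Named numeric vector `c(sensitivity = , ppv = )` in percent.
#' @export
#' @examples
#' recognition_stats(list(tp = 1399, fp = 35, fn = 30))
recognition_stats <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  stopifnot(is.numeric(tp), is.numeric(fp), is.numeric(fn))
  if (tp + fn <= 0 || tp + fp <= 0)
    stop("undefined statistic: zero denominator", call. = FALSE)
  c(sensitivity = tp / (tp + fn) * 100, ppv = tp / (tp + fp) * 100)
}

#' Inter-beat intervals of an event series
#'
#' Time differences between consecutive events, in milliseconds, stamped
#' with the later event's time.
#'
#' @param events An [event_series()] with at least 2 events.
#' @return A [tachogram()] with all intervals marked valid.
#' @export
#' @examples
#' inter_beat_intervals(event_series(c(0, 0.8, 1.7), "S1"))
inter_beat_intervals <- function(events) {
  stopifnot(inherits(events, "event_series"))
  t <- events$times
  if (length(t) < 2)
    stop("need at least 2 events to form intervals", call. = FALSE)
  tachogram(diff(t) * 1000, times = t[-1])
}

#' Paired valid inter-beat intervals
#'
#' Returns the reference/detected interval pairs that survive the exclusion
#' rule: an interval pair is kept only when both detected events bounding it
#' are true positives matched to *consecutive* reference beats. Every
#' interval touching a false detection, or flanking a missed beat, is
#' dropped. The input tachograms' `valid_mask`s are updated accordingly (by
#' value; the masked copies are returned).
#'
#' @param det_tacho [tachogram()] from the detected events (length
#'   `n_detected - 1`).
#' @param ref_tacho [tachogram()] from the reference events (length
#'   `n_reference - 1`).
#' @param match The `beat_match` pairing the two event series.
#' @return A list with `x` (reference intervals, ms), `y` (detected
#'   intervals, ms), `det_tacho`, `ref_tacho` (masked copies).
#' @export
paired_valid_intervals <- function(det_tacho, ref_tacho, match) {
  stopifnot(inherits(det_tacho, "tachogram"),
            inherits(ref_tacho, "tachogram"),
            inherits(match, "beat_match"))
  if (length(det_tacho) != match$n_detected - 1L)
    stop("detected tachogram inconsistent with match", call. = FALSE)
  if (length(ref_tacho) != match$n_reference - 1L)
    stop("reference tachogram inconsistent with match", call. = FALSE)
  a <- match$assignments
  nref <- match$n_reference
  ref_keep <- logical(max(nref - 1L, 0L))
  det_keep <- logical(length(det_tacho))
  x <- numeric(0); y <- numeric(0)
  for (k in seq_len(nref - 1L)) {
    d1 <- a[k]; d2 <- a[k + 1L]
    # both bounding beats detected, and their detections consecutive
    if (!is.na(d1) && !is.na(d2) && d2 == d1 + 1L) {
      ref_keep[k] <- TRUE
      det_keep[d1] <- TRUE  # detected interval (d1, d1+1) has index d1
      x <- c(x, ref_tacho$intervals[k])
      y <- c(y, det_tacho$intervals[d1])
    }
  }
  det_tacho$valid_mask <- det_keep
  ref_tacho$valid_mask <- ref_keep
  list(x = x, y = y, det_tacho = det_tacho, ref_tacho = ref_tacho)
}
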