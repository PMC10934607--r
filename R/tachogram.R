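#' Tachogram: a series of inter-beat intervals
#'
#' The substrate of agreement and heart-rate-variability analysis: positive
#' inter-beat intervals in milliseconds, each stamped with the occurrence
#' time of the interval's second (later) event, plus a per-interval validity
#' flag used to exclude intervals adjacent to detection errors.
#'
#' @param intervals Numeric vector of inter-beat intervals in ms, all > 0.
#' @param times Numeric vector of the same length: time (s) of the later
#'   event bounding each interval.
#' @param valid_mask Logical vector of the same length (default all `TRUE`).
#' @return An object of class `tachogram`.
#' @export
#' @examples
#' tachogram(c(800, 820, 810), times = c(0.8, 1.62, 2.43))
tachogram <- function(intervals, times, valid_mask = NULL) {
  intervals <- as.numeric(intervals)
  times <- as.numeric(times)
  if (length(intervals) != length(times))
    stop("`intervals` and `times` must have equal length", call. = FALSE)
  if (length(intervals) && any(intervals <= 0))
    stop("all intervals must be positive", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(intervals))
  if (length(valid_mask) != length(intervals))
    stop("`valid_mask` length mismatch", call. = FALSE)
  structure(list(intervals = intervals, times = times,
                 valid_mask = as.logical(valid_mask)),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d intervals, mean RR %.1f ms, %d flagged invalid\n",
              length(x$intervals),
              if (length(x$intervals)) mean(x$intervals) else NA_real_,
              sum(!x$valid_mask)))
  invisible(x)
}

#' @export
length.tachogram <- function(x) length(x$intervals)

#' @export
plot.tachogram <- function(x, ..., xlab = "time (s)", ylab = "RR (ms)") {
  graphics::plot(x$times, x$intervals, type = "b", pch = 20,
                 col = ifelse(x$valid_mask, "black", "red"),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
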