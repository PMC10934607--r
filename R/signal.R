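#' Uniformly sampled signal
#'
#' Container for a 1-D uniformly sampled real-valued trace. All processing
#' functions in the package consume and return this class, so sampling-rate
#' bookkeeping travels with the samples.
#'
#' @param samples Numeric vector of sample values (signal units). All values
#'   must be finite and there must be at least 2 of them.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `uniform_signal`: a list with elements
#'   `samples`, `fs` and `t0`.
#' @export
#' @examples
#' s <- uniform_signal(sin(2 * pi * 1 * seq(0, 1, by = 0.01)), fs = 100)
#' s
uniform_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(samples) < 2L)
    stop("a signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number", call. = FALSE)
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$samples)

#' Sample times of a signal
#'
#' @param x A [uniform_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Duration of a signal in seconds
#' @param x A [uniform_signal()].
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  length(x$samples) / x$fs
}

#' @export
plot.uniform_signal <- function(x, ..., xlab = "time (s)", ylab = "value",
                                type = "l") {
  graphics::plot(signal_times(x), x$samples, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding.
# Padding mirrors the signal about its endpoints (2*x[1] - x[k]) for
# pad_len samples on each side before the two filter passes, which keeps the
# passes from ringing into the analysis window. pad_len defaults to 3x the
# filter length, the conventional choice for forward-backward filtering.
zero_phase <- function(b, a, x, pad_len = NULL) {
  n <- length(x)
  if (is.null(pad_len)) pad_len <- 3L * (max(length(b), length(a)) - 1L)
  pad_len <- min(pad_len, n - 1L)
  if (pad_len > 0) {
    head_pad <- 2 * x[1] - x[(pad_len + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - pad_len)]
    xe <- c(head_pad, x, tail_pad)
  } else {
    xe <- x
  }
  fwd <- signal::filter(b, a, xe)
  bwd <- rev(signal::filter(b, a, rev(fwd)))
  as.numeric(bwd[(pad_len + 1):(pad_len + n)])
}

# Apply a designed signal::butter filter zero-phase to a uniform_signal,
# preserving length, fs and t0.
apply_zero_phase <- function(sig, filt, pad_len = NULL) {
  uniform_signal(zero_phase(filt$b, filt$a, sig$samples, pad_len = pad_len),
                 fs = sig$fs, t0 = sig$t0)
}

#' Series of event timestamps
#'
#' Strictly increasing event times with a label identifying the event type
#' (R-peaks or localized heart sounds).
#'
#' @param times Numeric vector of event times in seconds, strictly
#'   increasing. May be empty.
#' @param label One of `"R"`, `"S1"`, `"S2"`, `"S1S2"`.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, label = c("R", "S1", "S2", "S1S2")) {
  label <- match.arg(label)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (length(times) && !all(is.finite(times)))
    stop("event times must be finite", call. = FALSE)
  structure(list(times = times, label = label), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d %s events", length(x$times), x$label))
  if (length(x$times))
    cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards so library code never perturbs a session.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
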