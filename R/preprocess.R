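#' Extract the respiratory component of a raw FCG signal
#'
#' The raw force-sensor trace is dominated by a slow respiratory baseline on
#' which the cardiac vibrations ride. The baseline is estimated by
#' Savitzky-Golay smoothing with a frame of about 1.5 s, long enough to
#' average out cardiac activity while tracking breathing (typically
#' 0.1-0.5 Hz).
#'
#' @param raw A [uniform_signal()], the raw FCG sensor signal.
#' @param frame_s Smoothing frame length in seconds (default 1.5). The actual
#'   frame is the nearest odd number of samples.
#' @param polyorder Polynomial order of the local fit (default 3).
#' @return A [uniform_signal()] of the same length and sampling rate: the
#'   respiratory component.
#' @export
#' @examples
#' fs <- 200
#' t <- seq(0, 10, by = 1 / fs)
#' raw <- uniform_signal(sin(2 * pi * 0.25 * t) + 0.1 * rnorm(length(t)), fs)
#' resp <- extract_respiratory(raw)
extract_respiratory <- function(raw, frame_s = 1.5, polyorder = 3) {
  stopifnot(inherits(raw, "uniform_signal"))
  n <- round(frame_s * raw$fs)
  if (n %% 2 == 0) n <- n + 1
  if (n < polyorder + 2)
    stop("frame too short for the requested polynomial order", call. = FALSE)
  if (n > length(raw$samples))
    stop("smoothing frame longer than the signal", call. = FALSE)
  sm <- signal::sgolayfilt(raw$samples, p = polyorder, n = n)
  uniform_signal(sm, fs = raw$fs, t0 = raw$t0)
}

#' Remove the respiratory baseline from a raw FCG signal
#'
#' Sample-wise subtraction of the respiratory component, yielding the FCG
#' cardiac component.
#'
#' @param raw A [uniform_signal()], the raw FCG sensor signal.
#' @param resp A [uniform_signal()] of equal length and sampling rate, the
#'   respiratory component (see [extract_respiratory()]).
#' @return A [uniform_signal()]: the cardiac component `raw - resp`.
#' @export
remove_baseline <- function(raw, resp) {
  stopifnot(inherits(raw, "uniform_signal"), inherits(resp, "uniform_signal"))
  if (length(raw$samples) != length(resp$samples))
    stop("`raw` and `resp` must have equal length", call. = FALSE)
  if (raw$fs != resp$fs)
    stop("`raw` and `resp` must share the sampling rate", call. = FALSE)
  uniform_signal(raw$samples - resp$samples, fs = raw$fs, t0 = raw$t0)
}

#' Isolate the heart-sound component of the FCG cardiac signal
#'
#' Zero-phase 4th-order Butterworth band-pass. The 30-200 Hz default passes
#' the oscillatory S1/S2 bursts while rejecting both the infrasonic cardiac
#' wall motion below 30 Hz and high-frequency noise.
#'
#' @param fcg A [uniform_signal()], the FCG cardiac component.
#' @param lo,hi Band edges in Hz (defaults 30 and 200).
#' @param half_order Butterworth half-order; the resulting band-pass has
#'   order `2 * half_order` (default 2, i.e. a 4th-order band-pass).
#' @return A [uniform_signal()] of the same length: the heart-sound
#'   component (HS-FCG).
#' @export
bandpass_heart_sounds <- function(fcg, lo = 30, hi = 200, half_order = 2) {
  stopifnot(inherits(fcg, "uniform_signal"))
  nyq <- fcg$fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) stop("`hi` must be below fs/2", call. = FALSE)
  bf <- signal::butter(half_order, c(lo, hi) / nyq, type = "pass")
  apply_zero_phase(fcg, bf, pad_len = max(6L * half_order, round(0.5 * fcg$fs)))
}

#' Condition a raw ECG trace
#'
#' Zero-phase 4th-order Butterworth band-pass (0.5-40 Hz by default)
#' followed by notch filters at the mains frequency and its harmonics. The
#' mains fundamental is always notched (the band-pass roll-off alone leaves
#' a substantial 50 Hz residue); higher harmonics at or above the Nyquist
#' frequency or above the band-pass upper edge are skipped, since the
#' band-pass already removes them.
#'
#' @param raw_ecg A [uniform_signal()], the raw ECG lead.
#' @param lo,hi Band edges in Hz (defaults 0.5 and 40).
#' @param mains Powerline frequency in Hz (default 50).
#' @param n_harmonics Number of mains harmonics considered, including the
#'   fundamental (default 3).
#' @param q Notch quality factor: each notch is a 2nd-order band-stop of
#'   width `f0 / q` (default 30).
#' @param half_order Butterworth half-order of the band-pass (default 2).
#' @return A [uniform_signal()] of the same length: the conditioned ECG.
#' @export
preprocess_ecg <- function(raw_ecg, lo = 0.5, hi = 40, mains = 50,
                           n_harmonics = 3, q = 30, half_order = 2) {
  stopifnot(inherits(raw_ecg, "uniform_signal"))
  nyq <- raw_ecg$fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) stop("`hi` must be below fs/2", call. = FALSE)
  if (mains >= nyq) stop("`mains` must be below fs/2", call. = FALSE)
  bf <- signal::butter(half_order, c(lo, hi) / nyq, type = "pass")
  out <- apply_zero_phase(raw_ecg, bf,
                          pad_len = max(6L * half_order,
                                        round(0.5 * raw_ecg$fs)))
  for (k in seq_len(n_harmonics)) {
    f0 <- k * mains
    if (f0 >= nyq) next
    if (k > 1 && f0 > hi) next
    bw <- f0 / q
    edges <- c(f0 - bw / 2, f0 + bw / 2) / nyq
    nf <- signal::butter(2, edges, type = "stop")
    out <- apply_zero_phase(out, nf)
  }
  out
}
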