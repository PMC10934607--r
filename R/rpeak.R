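#' Detect R-peaks in a conditioned ECG
#'
#' Classic Pan-Tompkins stages: a 5-15 Hz band-pass emphasizing the QRS
#' complex, a 5-point derivative, squaring, and a 150 ms moving-window
#' integration, followed by adaptive dual-threshold peak picking with
#' search-back. Signal and noise levels adapt as
#' `SPK = 0.125 * peak + 0.875 * SPK` (noise analogously), with
#' `T1 = NPK + 0.25 * (SPK - NPK)` and the search-back threshold
#' `T2 = 0.5 * T1`: when no QRS is found within 1.66 times the running
#' average RR, the largest candidate above `T2` in the gap is accepted.
#' Each accepted detection is refined to the local maximum of the
#' conditioned ECG within +/- 50 ms, and detections closer than
#' `refractory_s` are suppressed (larger peak wins).
#'
#' @param ecg A [uniform_signal()], the conditioned ECG
#'   (see [preprocess_ecg()]), at least 2 s long, `fs >= 100` Hz.
#' @param refractory_s Minimum separation between detections in seconds
#'   (default 0.25).
#' @return An [event_series()] labelled `"R"`. A flat signal yields an
#'   empty series.
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.25) {
  stopifnot(inherits(ecg, "uniform_signal"))
  fs <- ecg$fs
  if (fs < 100) stop("ECG sampling rate must be >= 100 Hz", call. = FALSE)
  if (signal_duration(ecg) < 2)
    stop("need at least 2 s of ECG", call. = FALSE)
  x <- ecg$samples
  if (max(x) == min(x)) return(event_series(numeric(0), "R"))

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- zero_phase(bf$b, bf$a, x, pad_len = round(0.5 * fs))
  # 5-point derivative: (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4])
  dv <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  dv[is.na(dv)] <- 0
  sq <- as.numeric(dv)^2
  w <- max(2L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                  mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  if (!length(cand)) return(event_series(numeric(0), "R"))

  # adaptive dual thresholds over the integrated signal
  init_seg <- mwi[seq_len(min(n, round(2 * fs)))]
  spk <- max(init_seg) * 0.5
  npk <- mean(init_seg) * 0.5
  refr <- round(0.2 * fs)
  qrs <- integer(0)
  rr_avg <- NA_real_
  last_qrs <- -Inf
  pending <- integer(0)  # sub-threshold candidates since the last QRS
  for (i in cand) {
    p <- mwi[i]
    t1 <- npk + 0.25 * (spk - npk)
    if (i - last_qrs <= refr) next
    if (p >= t1) {
      qrs <- c(qrs, i)
      spk <- 0.125 * p + 0.875 * spk
      if (length(qrs) >= 2) {
        rr_new <- i - last_qrs
        rr_avg <- if (is.na(rr_avg)) rr_new else 0.875 * rr_avg + 0.125 * rr_new
      }
      last_qrs <- i
      pending <- integer(0)
    } else {
      npk <- 0.125 * p + 0.875 * npk
      pending <- c(pending, i)
      # search-back: if the expected beat is overdue, take the best
      # sub-threshold candidate above T2
      if (!is.na(rr_avg) && i - last_qrs > 1.66 * rr_avg &&
          length(pending)) {
        t2 <- 0.5 * (npk + 0.25 * (spk - npk))
        ok <- pending[mwi[pending] >= t2 & pending - last_qrs > refr]
        if (length(ok)) {
          best <- ok[which.max(mwi[ok])]
          qrs <- sort(c(qrs, best))
          spk <- 0.25 * mwi[best] + 0.75 * spk
          rr_new <- best - last_qrs
          rr_avg <- 0.875 * rr_avg + 0.125 * rr_new
          last_qrs <- max(qrs)
          pending <- pending[pending > best]
        }
      }
    }
  }
  if (!length(qrs)) return(event_series(numeric(0), "R"))

  # map each integrator peak back to the QRS: the R wave lies inside the
  # moving-integration window that produced the peak, so anchor on the
  # conditioned-ECG maximum over [i - w, i], then refine to the local
  # maximum within +/- 50 ms
  half <- round(0.050 * fs)
  refined <- vapply(qrs, function(i) {
    a0 <- max(1, i - w)
    anchor <- a0 + which.max(x[a0:min(length(x), i)]) - 1
    c0 <- max(1, anchor - half)
    c1 <- min(length(x), anchor + half)
    as.integer(c0 + which.max(x[c0:c1]) - 1)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period: larger conditioned-ECG peak wins
  if (length(refined) > 1) {
    ord <- refined[order(-x[refined], refined)]
    min_gap <- refractory_s * fs
    keep <- integer(0)
    for (i in ord)
      if (!length(keep) || all(abs(keep - i) >= min_gap))
        keep <- c(keep, i)
    refined <- sort(keep)
  }
  event_series(ecg$t0 + (refined - 1) / fs, "R")
}
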