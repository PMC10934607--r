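#' Configuration for the synthetic FCG/ECG generator
#'
#' Collects every knob of the synthetic recording generator and validates
#' the combination. The generator emulates the second-order structure a
#' heart-sound localizer faces in force-sensor chest recordings:
#' quasi-periodic S1 and S2 oscillatory bursts (S1 larger, S2 later in the
#' beat), a slow respiratory baseline, respiratory amplitude modulation of
#' S2, broadband noise, and a concurrent ECG whose R-peaks precede S1 by an
#' electromechanical delay.
#'
#' @param fs Sampling rate in Hz (default 1000; ample for 30-200 Hz
#'   heart-sound content).
#' @param duration Recording length in s (default 300).
#' @param hr_mean Mean heart rate in bpm (default 65).
#' @param rr_jitter_sd SD of the white Gaussian RR perturbation in ms
#'   (default 20, resting short-term variability).
#' @param resp_rate Respiratory rate in Hz (default 0.25, i.e. 15
#'   breaths/min).
#' @param rsa_amp Amplitude of the respiratory sinus-arrhythmia RR
#'   modulation in ms (default 40).
#' @param s1_freq,s2_freq Carrier frequencies of the Gaussian-modulated
#'   sinusoid wavelets in Hz (defaults 55 and 85: S1 is lower-pitched and
#'   longer than S2, which keeps the two sounds morphologically
#'   distinguishable under amplitude-invariant matching, and both carriers
#'   sit well inside the 30-200 Hz heart-sound band).
#' @param s1_dur,s2_dur Wavelet durations in s (defaults 0.12 and 0.06);
#'   the Gaussian envelope SD is `dur / 6`.
#' @param s2_delay_mean,s2_delay_sd Mean and SD of the S1-to-S2 systolic
#'   interval in s (defaults 0.30 and 0.005; systolic intervals are far
#'   more stable beat-to-beat than the cycle length).
#' @param s2_amp_ratio S2 peak amplitude relative to S1 (default 0.6,
#'   must be in (0, 1)).
#' @param resp_mod_depth Fractional respiratory modulation of the S2
#'   amplitude (default 0.2, i.e. +/-20 percent over the breath).
#' @param resp_baseline_amp Respiratory baseline amplitude in signal units
#'   (default 5; S1 peaks at 1).
#' @param noise_sd Broadband sensor-noise SD in signal units (default
#'   0.01, i.e. 40 dB below the unit S1 peak).
#' @param r_to_s1_delay Electromechanical delay from R-peak to S1 in s
#'   (default 0.05).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   signals and ground truth.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(fs = 1000, duration = 300, hr_mean = 65,
                         rr_jitter_sd = 20, resp_rate = 0.25, rsa_amp = 40,
                         s1_freq = 55, s2_freq = 85,
                         s1_dur = 0.12, s2_dur = 0.06,
                         s2_delay_mean = 0.30, s2_delay_sd = 0.005,
                         s2_amp_ratio = 0.6, resp_mod_depth = 0.2,
                         resp_baseline_amp = 5, noise_sd = 0.01,
                         r_to_s1_delay = 0.05, seed = 1L) {
  cfg <- list(fs = fs, duration = duration, hr_mean = hr_mean,
              rr_jitter_sd = rr_jitter_sd, resp_rate = resp_rate,
              rsa_amp = rsa_amp, s1_freq = s1_freq, s2_freq = s2_freq,
              s1_dur = s1_dur, s2_dur = s2_dur,
              s2_delay_mean = s2_delay_mean, s2_delay_sd = s2_delay_sd,
              s2_amp_ratio = s2_amp_ratio, resp_mod_depth = resp_mod_depth,
              resp_baseline_amp = resp_baseline_amp, noise_sd = noise_sd,
              r_to_s1_delay = r_to_s1_delay, seed = as.integer(seed))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in setdiff(names(cfg), "seed"))
    if (!num1(cfg[[nm]]))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  if (cfg$fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (cfg$duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (cfg$hr_mean <= 0) stop("`hr_mean` must be > 0", call. = FALSE)
  if (cfg$s2_amp_ratio <= 0 || cfg$s2_amp_ratio >= 1)
    stop("`s2_amp_ratio` must be in (0, 1)", call. = FALSE)
  if (cfg$s2_delay_mean <= cfg$s1_dur)
    stop("`s2_delay_mean` must exceed `s1_dur`", call. = FALSE)
  if (cfg$rr_jitter_sd < 0 || cfg$noise_sd < 0 || cfg$rsa_amp < 0)
    stop("noise and modulation amplitudes must be >= 0", call. = FALSE)
  if (cfg$r_to_s1_delay < 0)
    stop("`r_to_s1_delay` must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> fs %g Hz, %g s, HR %g bpm, ",
                     "RR jitter %g ms, RSA %g ms @ %g Hz, noise sd %g, ",
                     "seed %d\n"),
              x$fs, x$duration, x$hr_mean, x$rr_jitter_sd, x$rsa_amp,
              x$resp_rate, x$noise_sd, x$seed))
  invisible(x)
}

#' Ground-truth beat timings of a synthetic recording
#'
#' @param r_times,s1_times,s2_times Numeric vectors of equal length:
#'   R-peak, S1 and S2 times in seconds. For every beat `k`,
#'   `r_times[k] < s1_times[k] < s2_times[k] < r_times[k + 1]`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(r_times, s1_times, s2_times) {
  n <- length(r_times)
  if (length(s1_times) != n || length(s2_times) != n)
    stop("ground-truth series must have equal length", call. = FALSE)
  ok <- all(r_times < s1_times) && all(s1_times < s2_times) &&
    (n < 2 || all(s2_times[-n] < r_times[-1]))
  if (!ok)
    stop("beat ordering r < s1 < s2 < next r violated", call. = FALSE)
  structure(list(r_times = as.numeric(r_times),
                 s1_times = as.numeric(s1_times),
                 s2_times = as.numeric(s2_times)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats in [%.2f, %.2f] s\n",
              length(x$r_times),
              if (length(x$r_times)) min(x$r_times) else NA,
              if (length(x$r_times)) max(x$s2_times) else NA))
  invisible(x)
}

# Draw the RR series using the *current* RNG state. Beat k occurs at t_k;
# the interval that follows it is
#   RR_k = 60000/hr_mean + rsa_amp*sin(2*pi*resp_rate*t_k) + eps_k.
# Any RR <= 300 ms is redrawn (bounded retries) so the series stays
# physiological.
draw_rr <- function(config, max_retries = 100L) {
  base <- 60000 / config$hr_mean
  t_k <- 0
  rr <- numeric(0)
  times <- numeric(0)
  repeat {
    val <- NA_real_
    for (i in seq_len(max_retries)) {
      eps <- if (config$rr_jitter_sd > 0)
        stats::rnorm(1, 0, config$rr_jitter_sd) else 0
      cand <- base + config$rsa_amp * sin(2 * pi * config$resp_rate * t_k) + eps
      if (cand > 300) { val <- cand; break }
    }
    if (is.na(val))
      stop("cannot satisfy RR > 300 ms with this configuration",
           call. = FALSE)
    t_next <- t_k + val / 1000
    if (t_next > config$duration) break
    rr <- c(rr, val)
    times <- c(times, t_next)
    t_k <- t_next
  }
  tachogram(rr, times)
}

#' Generate a seeded synthetic RR-interval series
#'
#' The RR series is a constant mean interval plus a sinusoidal respiratory
#' sinus-arrhythmia modulation evaluated at each beat time plus white
#' Gaussian jitter. Intervals are constrained to exceed 300 ms by redrawing
#' the jitter (an unreachable constraint raises an error).
#'
#' @param config A [synth_config()].
#' @return A [tachogram()] whose `times` are the occurrence times of each
#'   interval's later beat (the first beat is at t = 0).
#' @export
#' @examples
#' rr <- generate_rr_series(synth_config(duration = 60, seed = 7))
#' rr
generate_rr_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, draw_rr(config))
}

# Gaussian-modulated cosine burst with envelope SD dur/6, truncated at
# +/- dur/2 (3 sigma). Peak value 1 at tau = 0, so the wavelet centre is its
# absolute maximum.
gm_wavelet <- function(tau, freq, dur) {
  sigma <- dur / 6
  env <- exp(-tau^2 / (2 * sigma^2))
  env[abs(tau) > dur / 2] <- 0
  env * cos(2 * pi * freq * tau)
}

# Add wavelet `w(t - centre)` into `x` (sample grid t0 = 0, rate fs).
add_burst <- function(x, fs, centre, half_width, fun) {
  i0 <- max(1L, floor((centre - half_width) * fs) + 1L)
  i1 <- min(length(x), ceiling((centre + half_width) * fs) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  tau <- (idx - 1) / fs - centre
  x[idx] <- x[idx] + fun(tau)
  x
}

#' Generate a synthetic FCG recording with ground truth
#'
#' Builds a raw FCG-like trace as a sum of S1 and S2 Gaussian-modulated
#' sinusoid bursts at the beat times drawn from the RR model, a sinusoidal
#' respiratory baseline, and white Gaussian noise. The S2 amplitude is
#' modulated over the respiratory cycle to emulate the beat-to-beat S2
#' morphology changes caused by physiologic splitting. R-peak times precede
#' each S1 by the configured electromechanical delay.
#'
#' @param config A [synth_config()].
#' @return A list with elements `signal` (a [uniform_signal()]) and
#'   `truth` (a [ground_truth()]).
#' @export
#' @examples
#' rec <- generate_fcg(synth_config(duration = 30, seed = 2))
#' rec$truth
generate_fcg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    rr <- draw_rr(config)
    # first beat sits clear of the edge; r_times must stay >= 0
    lead_in <- max(0.5, config$r_to_s1_delay + 0.1)
    s1 <- lead_in + c(0, cumsum(rr$intervals) / 1000)
    delays <- config$s2_delay_mean +
      if (config$s2_delay_sd > 0)
        stats::rnorm(length(s1), 0, config$s2_delay_sd) else 0
    delays <- pmax(delays, config$s1_dur + config$s2_dur / 2 + 0.02)
    s2 <- s1 + delays
    keep <- s2 + config$s2_dur / 2 < config$duration &
      s1 - config$s1_dur / 2 > 0
    s1 <- s1[keep]; s2 <- s2[keep]
    if (length(s1) < 2)
      stop("duration too short for at least 2 beats", call. = FALSE)
    n <- round(config$duration * config$fs)
    t <- (seq_len(n) - 1) / config$fs
    x <- numeric(n)
    a_k <- config$s2_amp_ratio *
      (1 + config$resp_mod_depth * sin(2 * pi * config$resp_rate * s2))
    for (k in seq_along(s1)) {
      x <- add_burst(x, config$fs, s1[k], config$s1_dur / 2,
                     function(tau) gm_wavelet(tau, config$s1_freq,
                                              config$s1_dur))
      x <- add_burst(x, config$fs, s2[k], config$s2_dur / 2,
                     function(tau) a_k[k] * gm_wavelet(tau, config$s2_freq,
                                                       config$s2_dur))
    }
    x <- x + config$resp_baseline_amp * sin(2 * pi * config$resp_rate * t)
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
    list(signal = uniform_signal(x, fs = config$fs),
         truth = ground_truth(s1 - config$r_to_s1_delay, s1, s2))
  })
}

#' Generate a synthetic ECG matching a ground truth
#'
#' Places a narrow positive QRS-like wavelet (Mexican hat, ~80 ms wide) at
#' each R-peak time, plus white Gaussian noise. With `noise_sd = 0` the
#' per-beat maximum falls exactly on the R-peak sample.
#'
#' @param config The [synth_config()] that produced `truth`.
#' @param truth A [ground_truth()] from [generate_fcg()].
#' @return A [uniform_signal()] of length `round(duration * fs)`.
#' @export
generate_ecg <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ground_truth"))
  sigma <- 0.02  # s; main lobe ~80 ms
  n <- round(config$duration * config$fs)
  x <- numeric(n)
  for (rk in truth$r_times)
    x <- add_burst(x, config$fs, rk, 4 * sigma,
                   function(tau) (1 - (tau / sigma)^2) *
                     exp(-tau^2 / (2 * sigma^2)))
  if (config$noise_sd > 0)
    x <- with_seed(config$seed + 1L,
                   x + stats::rnorm(n, 0, config$noise_sd))
  uniform_signal(x, fs = config$fs)
}

#' Generate a complete synthetic recording (FCG + ECG + truth)
#'
#' Convenience wrapper around [generate_fcg()] and [generate_ecg()].
#'
#' @param config A [synth_config()].
#' @return A list with `fcg`, `ecg` (both [uniform_signal()]) and `truth`
#'   (a [ground_truth()]).
#' @export
generate_recording <- function(config) {
  rec <- generate_fcg(config)
  list(fcg = rec$signal, ecg = generate_ecg(config, rec$truth),
       truth = rec$truth)
}
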