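#' Configuration of a full processing run
#'
#' Bundles the paths and parameters of the complete chain: preprocessing,
#' reference beat series (detected from the ECG or loaded from a
#' ground-truth file), template matching for the requested labels, beat
#' matching, agreement analysis and HRV comparison.
#'
#' @param fcg Path to the raw FCG CSV (see [read_signal_csv()]).
#' @param ecg Optional path to the concurrent ECG CSV.
#' @param truth Optional path to a ground-truth JSON (arrays `r_times`,
#'   `s1_times`, `s2_times`, seconds). One of `ecg`/`truth` is required:
#'   the reference beat series comes from R-peak detection on the ECG, or
#'   directly from `truth$r_times`.
#' @param out_dir Output directory; created if missing.
#' @param templates Named list with entries per label (`S1`, `S2`, `S1S2`),
#'   each either `list(start_s =, end_s =)` for a manual span on the
#'   heart-sound signal or `list(auto = TRUE)`.
#' @param fs Sampling rate for single-column CSVs.
#' @param sg_frame_s,sg_polyorder Respiratory Savitzky-Golay parameters.
#' @param hs_lo,hs_hi Heart-sound band edges in Hz.
#' @param min_height,min_distance_s NCC peak-picking parameters.
#' @param tol_s Beat-matching tolerance in s.
#' @param hrv_threshold_ms Artifact-correction threshold in ms.
#' @param seed Seed for the stochastic internals (bootstrap CIs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fcg, ecg = NULL, truth = NULL, out_dir = ".",
                       templates = list(S1 = list(auto = TRUE),
                                        S2 = list(auto = TRUE),
                                        S1S2 = list(auto = TRUE)),
                       fs = NULL, sg_frame_s = 1.5, sg_polyorder = 3,
                       hs_lo = 30, hs_hi = 200,
                       min_height = 0.5, min_distance_s = 0.3,
                       tol_s = 0.15, hrv_threshold_ms = 250, seed = 1L) {
  if (is.null(ecg) && is.null(truth))
    stop("one of `ecg` or `truth` is required as beat reference",
         call. = FALSE)
  if (!file.exists(fcg)) stop("fcg file not found: ", fcg, call. = FALSE)
  for (p in c(ecg, truth))
    if (!is.null(p) && !file.exists(p))
      stop("file not found: ", p, call. = FALSE)
  bad <- setdiff(names(templates), c("S1", "S2", "S1S2"))
  if (length(bad))
    stop("unknown template label: ", bad[1], call. = FALSE)
  if (!length(templates))
    stop("at least one template spec is required", call. = FALSE)
  structure(list(fcg = fcg, ecg = ecg, truth = truth, out_dir = out_dir,
                 templates = templates, fs = fs, sg_frame_s = sg_frame_s,
                 sg_polyorder = sg_polyorder, hs_lo = hs_lo, hs_hi = hs_hi,
                 min_height = min_height, min_distance_s = min_distance_s,
                 tol_s = tol_s, hrv_threshold_ms = hrv_threshold_ms,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full heart-sound localization and evaluation pipeline
#'
#' Executes, in order: respiratory baseline extraction and removal,
#' heart-sound band-pass, reference beat series (Pan-Tompkins on the ECG or
#' the ground-truth R-times), template matching per requested label, beat
#' matching with recognition statistics, inter-beat-interval agreement
#' analysis on the valid interval pairs, and HRV reports (reference vs
#' detected; detection-error intervals are retained there, before artifact
#' correction). Writes `events.json`, `stats.json`, `agreement.json` and
#' `hrv.json` to `out_dir`.
#'
#' @param config A [run_config()].
#' @param verbose Log each stage to the console (default `TRUE`).
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[preprocess] reading %s", config$fcg)
  raw <- read_signal_csv(config$fcg, fs = config$fs)
  resp <- extract_respiratory(raw, frame_s = config$sg_frame_s,
                              polyorder = config$sg_polyorder)
  cardiac <- remove_baseline(raw, resp)
  hs <- bandpass_heart_sounds(cardiac, lo = config$hs_lo, hi = config$hs_hi)
  say("[preprocess] %d samples @ %g Hz", length(hs$samples), hs$fs)

  if (!is.null(config$truth)) {
    tr <- jsonlite::read_json(config$truth, simplifyVector = TRUE)
    reference <- event_series(tr$r_times, "R")
    say("[reference] %d ground-truth R-times", length(reference))
  } else {
    ecg_raw <- read_signal_csv(config$ecg, fs = config$fs)
    ecg <- preprocess_ecg(ecg_raw)
    reference <- detect_r_peaks(ecg)
    say("[rpeak] %d R-peaks detected", length(reference))
  }
  if (length(reference) < 3)
    stop("stage reference: too few reference beats", call. = FALSE)
  ref_tacho <- inter_beat_intervals(reference)

  events_out <- list()
  stats_out <- list()
  agreement_out <- list()
  hrv_out <- list(reference = unclass(hrv_report(
    ref_tacho, threshold_ms = config$hrv_threshold_ms)))
  results <- list(heart_sounds = hs, reference = reference)

  for (label in names(config$templates)) {
    spec <- config$templates[[label]]
    tpl <- if (isTRUE(spec$auto)) {
      auto_select_template(hs, label)
    } else {
      if (is.null(spec$start_s) || is.null(spec$end_s))
        stop(sprintf("stage matcher(%s): template spec needs start_s/end_s or auto",
                     label), call. = FALSE)
      extract_template(hs, spec$start_s, spec$end_s, label)
    }
    ev <- detect_events(hs, tpl, min_height = config$min_height,
                        min_distance_s = config$min_distance_s)
    say("[matcher] %s: %d events", label, length(ev))
    events_out[[label]] <- round(ev$times, 6)
    if (length(ev) < 3) {
      say("[beats] %s: too few events, skipping evaluation", label)
      next
    }
    m <- match_events(ev, reference, tol_s = config$tol_s)
    st <- recognition_stats(m)
    det_tacho <- inter_beat_intervals(ev)
    paired <- paired_valid_intervals(det_tacho, ref_tacho, m)
    stats_out[[label]] <- list(
      tp = m$tp, fp = m$fp, fn = m$fn,
      sensitivity = round(st[["sensitivity"]], 1),
      ppv = round(st[["ppv"]], 1),
      n_intervals = length(paired$x),
      intervals_ref_ms = round(paired$x, 3),
      intervals_det_ms = round(paired$y, 3))
    say("[beats] %s: TP %d FP %d FN %d (Se %.1f%%, PPV %.1f%%)",
        label, m$tp, m$fp, m$fn, st[["sensitivity"]], st[["ppv"]])
    if (length(paired$x) >= 10) {
      ag <- agreement_analysis(paired$x, paired$y, seed = config$seed)
      agreement_out[[label]] <- list(
        n = ag$regression$n,
        r = ag$correlation$r, r_ci = ag$correlation$ci,
        slope = ag$regression$slope, slope_ci = ag$regression$slope_ci,
        intercept = ag$regression$intercept,
        intercept_ci = ag$regression$intercept_ci,
        cusum_linear = ag$regression$cusum$linear,
        bias = ag$bland_altman$bias, bias_ci = ag$bland_altman$bias_ci,
        loa = c(ag$bland_altman$loa_low, ag$bland_altman$loa_high),
        loa_low_ci = ag$bland_altman$loa_low_ci,
        loa_high_ci = ag$bland_altman$loa_high_ci,
        normal_differences = ag$bland_altman$normal)
    }
    # HRV on the detected series keeps error-affected intervals; artifact
    # correction inside hrv_report handles them
    hrv_out[[label]] <- unclass(hrv_report(
      det_tacho, threshold_ms = config$hrv_threshold_ms))
    results[[label]] <- list(template = tpl, events = ev, match = m,
                             paired = paired)
  }

  write_json_output(events_out, file.path(config$out_dir, "events.json"),
                    schema = "events")
  write_json_output(stats_out, file.path(config$out_dir, "stats.json"),
                    schema = "stats")
  write_json_output(agreement_out,
                    file.path(config$out_dir, "agreement.json"),
                    schema = "agreement")
  write_json_output(hrv_out, file.path(config$out_dir, "hrv.json"),
                    schema = "hrv")
  say("[done] outputs in %s", config$out_dir)
  invisible(c(results, list(events = events_out, stats = stats_out,
                            agreement = agreement_out, hrv = hrv_out)))
}
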