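---
title: "Template matching for heart-sound localization in forcecardiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template matching for heart-sound localization in forcecardiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcghs)
```

## The problem

Forcecardiography (FCG) records the local forces that cardiac and
respiratory activity induce on the chest wall through a small force sensor
taped to the thorax. The raw trace superimposes a large, slow respiratory
component, infrasonic cardiac wall motion, and the oscillatory bursts of
the first and second heart sounds (S1, at the onset of ventricular systole;
S2, at the onset of diastole). Localizing S1 and S2 — and telling them
apart — turns a single chest-contact sensor into a beat-by-beat monitor:
consecutive like events give inter-beat intervals, and those intervals
support full heart-rate-variability (HRV) analysis without an ECG.

`fcghs` implements a template-matching localizer for this setting, together
with the complete evaluation stack used to judge it: recognition
statistics against a reference beat series, non-parametric method-comparison
of the interval series (Passing-Bablok regression, correlation,
Bland-Altman limits of agreement), and a standard HRV index set.

## The processing chain

1. **Respiratory baseline.** A Savitzky-Golay filter (frame ~1.5 s,
   polynomial order 3) tracks the slow respiratory component, which is then
   subtracted. The frame length is long enough to average out cardiac
   activity while following breathing at typical rates; the polynomial
   order is the standard low-order choice for smooth baselines and is
   exposed as a parameter. With a respiration-dominated raw signal
   (amplitude several times the heart sounds) roughly half a percent of the
   baseline survives the subtraction; that residue lives below 1 Hz, so the
   next stage removes it completely and the heart-sound chain never sees
   it.
2. **Heart-sound band.** A 4th-order Butterworth band-pass, 30-200 Hz,
   applied forward-backward (zero phase, so event timings are not skewed by
   group delay), isolates the heart-sound component. "4th order" is read
   as the order of the designed filter; the forward-backward pass squares
   its magnitude response. Edge effects are controlled by odd-reflection
   padding.
3. **Reference beats.** The concurrent ECG is band-passed 0.5-40 Hz (zero
   phase) and notched at the mains frequency; R-peaks are located with the
   classic Pan-Tompkins stages (5-15 Hz band-pass, five-point derivative,
   squaring, 150 ms moving-window integration, adaptive dual thresholds
   with search-back). Each detection is mapped back to the conditioned-ECG
   maximum inside the trailing integration window and refined to the local
   maximum within ±50 ms. The mains notch is always applied at the
   fundamental: the 0.5-40 Hz band-pass alone leaves a ~28% residue at
   50 Hz, far too much next to R-wave amplitudes.
4. **Template matching.** A template — a signal excerpt enclosing all the
   oscillations of S1, of S2, or of a whole S1-S2 pair plus short tracts on
   either side — is slid along the heart-sound signal, computing at each
   position the zero-mean normalized cross-correlation (NCC)

   $$v_k \;=\; \frac{\sum_i (x_{k+i} - \bar x_k)\,(t_i - \bar t)}
   {\sqrt{\sum_i (x_{k+i} - \bar x_k)^2 \;\sum_i (t_i - \bar t)^2}} \in [-1, 1],$$

   which responds to morphology and is invariant to amplitude scale and
   offset. Local maxima of the NCC trace at or above 0.5, thinned by a
   0.3 s refractory rule (higher peak wins; ties go to the earlier one),
   are the detected events. Each trace is re-aligned by the position of the
   template's absolute maximum, so an event time marks where that maximum
   lands on the signal — making S1-, S2- and pair-template outputs directly
   comparable. The sliding sums use an FFT cross-correlation padded to a
   2-3-5-smooth length, with an exact `O(NM)` formulation used as the test
   oracle.
5. **Evaluation.** Detections are paired one-to-one with reference beats
   after self-calibrating the expected electromechanical lag (median of
   nearest-neighbour offsets), accepting residuals up to ±150 ms;
   sensitivity and positive predictive value follow from the TP/FP/FN
   bookkeeping. For interval agreement, only interval pairs whose bounding
   detections are true positives matched to consecutive reference beats
   enter the analysis; everything touching a false or missed event is
   excluded. For the HRV comparison those intervals are *retained* instead,
   and the artifact-correction step is left to repair them — matching how
   such tachograms are treated in practice.

## Numerical and statistical choices

* **NCC on near-silent windows.** Zero-variance windows map to similarity
  0. Because NCC is amplitude-invariant, a window of pure sensor noise in
  an otherwise silent stretch scores like any other noise — at *any* noise
  amplitude — so the same neutralization is applied to windows whose
  centred RMS falls below 3% of the loudest window's (`flat_tol`,
  settable to 0 for the textbook definition). Without this, spurious NCC
  peaks above 0.5 appear in silent diastole no matter how small the noise.
* **Passing-Bablok.** The slope is the shifted median of pairwise slopes
  (ties in x and slopes of exactly −1 excluded, offset by the count of
  slopes below −1), with the original rank-based normal-approximation
  confidence intervals; the cusum linearity test walks the residual signs
  in ascending-x order and compares the maximal excursion, scaled by
  `sqrt(L + 1)`, against the Kolmogorov-Smirnov critical value (1.22 at
  the 0.10 level).
* **Bland-Altman.** Differences are gated by Shapiro-Wilk at 0.05: normal
  differences use mean ± 1.96 SD with t-based interval estimates (bias SE
  `s/sqrt(n)`, limit SE `s*sqrt(3/n)`); non-normal differences use the
  median and the 2.5th/97.5th percentiles (type-7 quantiles) with seeded
  bootstrap intervals (2000 resamples).
* **HRV conventions.** SDNN uses the sample SD; RMSSD uses the raw second
  moment of successive differences, and SD1 is defined as
  `RMSSD/sqrt(2)` so the Poincaré-RMSSD identity holds exactly for every
  tachogram; SD2 follows from `2*SDNN^2 = SD1^2 + SD2^2`. Min/max heart
  rate are taken on a 5-beat moving average. The spectrum interpolates the
  tachogram at 4 Hz (cubic spline), detrends with smoothness priors
  (second-difference penalty, lambda = 500), and uses Welch's method (Hann
  window, 150 s segments or the full record if shorter, 50% overlap);
  band powers integrate VLF 0-0.04, LF 0.04-0.15, HF 0.15-0.4 Hz. ApEn
  includes self-matches (Pincus); SampEn excludes them (Richman-Moorman);
  both use Chebyshev distance with tolerance 0.2 SD.
* **DFA finite-size normalization.** For linearly detrended uncorrelated
  noise the expected squared residual per point at box size `s` is
  proportional to `(s^2 - 4)/(6s)`, not `s/6` (verified by simulation to
  four digits). Fitting `log F` over boxes 4-16 without accounting for
  this biases the white-noise exponent to ~0.59. The fluctuation function
  is therefore normalized by `sqrt(1 - 4/s^2)`, after which white noise
  scales as `s^{0.5}` across the whole short range; at the long-range
  boxes (16-64) the factor is under 2% and immaterial.
* **Artifact correction.** An interval deviating more than 250 ms from the
  median of its 11-interval centred window is replaced by cubic-spline
  interpolation over its neighbours, one pass; flagging more than 20% of
  intervals raises a quality warning rather than an error.

## The synthetic-data generator

Real FCG recordings of this kind are not publicly available, so validation
rests on a seeded generator that emulates the statistical structure the
method assumes:

* beat times from `RR_k = 60000/HR + A_RSA * sin(2*pi*f_resp*t_k) + eps_k`
  (defaults: 65 bpm, 40 ms respiratory sinus arrhythmia at 0.25 Hz, 20 ms
  white jitter, intervals constrained above 300 ms);
* S1 and S2 as Gaussian-modulated cosine bursts (envelope SD = duration/6)
  whose centre is their absolute maximum; S2 follows S1 by 300 ± 5 ms —
  systolic intervals are far more stable beat-to-beat than the cycle
  length — at 0.6 relative amplitude, modulated ±20% over the respiratory
  cycle to emulate the morphology changes of physiologic S2 splitting;
* a respiratory baseline (amplitude 5, i.e. respiration dominates the raw
  trace) and white sensor noise (SD 0.01, 40 dB below the S1 peak);
* a concurrent ECG with a Mexican-hat QRS ~80 ms wide preceding each S1 by
  a 50 ms electromechanical delay.

Two generator parameters deserve comment. The wavelet carriers default to
55 Hz (S1, 0.12 s) and 85 Hz (S2, 0.06 s). Closely spaced carriers with
similar envelopes (e.g. 50 vs 60 Hz) produce wavelets whose mutual NCC
exceeds 0.8 — morphologically indistinguishable to an amplitude-invariant
matcher, which contradicts the premise that S1 and S2 differ in shape; the
defaults keep the cross-similarity near 0.2 while placing both carriers
well inside the 30-200 Hz analysis band (a 40 Hz carrier would lose 16% of
its energy at the band edge, distorting the very waveform the template is
cut from). Both choices are knobs, not constants.

What the generator does *not* emulate: broadband, chirp-like real heart
sounds (its bursts are narrowband, which makes NCC side lobes one carrier
period away more prominent than in real data — with systolic-delay jitter
the S1-S2 pair template can lock onto a lobe ~18 ms off for outlier
beats); S3/S4 sounds, murmurs, ectopy, posture changes, or non-stationary
noise. Passing the end-to-end tests therefore demonstrates the internal
consistency of the chain under the stated assumptions, not performance on
real recordings.

## Problem sizes used in validation

The end-to-end recovery runs on a 5-minute recording at 1 kHz (~325
beats): ample for every stage including the spectral HRV indices (which
need at least 2 minutes), while keeping the whole suite fast. Oracle
comparisons (NCC, Passing-Bablok, entropies) use small instances where an
exact `O(n^2)` reference is trivial; stochastic recovery checks
(Bland-Altman, DFA) use n = 500-1000.

## Known limitations

* Detection thresholds (NCC >= 0.5, 0.3 s refractory) are sensible defaults
  for resting recordings up to ~200 bpm, not tuned constants.
* The S1-S2 pair template inherits the narrowband lobe ambiguity described
  above on synthetic data.
* The HRV spectrum follows one fixed recipe (4 Hz resampling, smoothness
  priors, Welch); no time-varying spectra.
* Reference R-peak detection assumes an upright QRS of roughly normal
  width; no arrhythmia handling.
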