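---
title: "Fiducial-point extraction for PPG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-point extraction for PPG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgfiducial)
```

This vignette is the package's own account of its methods: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic generator does and does not emulate, and where
the design was genuinely open.

## The pipeline

A raw PPG record passes through five stages:

1. **Bandpass conditioning.** A 4th-order Chebyshev type-II filter with
   20 dB stopband attenuation and edges at 0.4 and 8 Hz, applied
   forward–backward (zero phase).  Chebyshev type II keeps the passband
   monotone and flat — important because amplitude features are exported —
   while the zero-phase application guarantees that no landmark is shifted
   by phase delay.  The design is kept in pole–zero form and realized as a
   cascade of biquad sections: at a normalized low edge of 0.4/500 the
   single transfer-function polynomial is so ill-conditioned that a rounded
   pole leaves the unit circle and the recursion diverges, whereas the
   cascade is stable and reproduces the designed response to within
   numerical noise (the test suite checks the realized response against the
   analytic one).  Edge transients are handled by symmetric-reflection
   padding plus steady-state initialization of each section.

2. **Smoothing.** Centered moving averages (MATLAB `movmean` semantics:
   shrinking windows at the edges): 25 ms on the filtered pulse and 30 ms
   on each difference-based derivative.  The derivative window is the
   larger of the two because differencing amplifies high-frequency noise by
   a factor that grows with frequency; 30 ms attenuates 4 Hz content — the
   top of the morphological band — by less than 2%, while suppressing the
   residual ripple near the 8 Hz stopband edge that would otherwise litter
   the jerk waveform with spurious zero-crossings.  Both windows are
   exposed in `ppg_control()`.

3. **Quality screening and beat extraction.**  The skewness SQI (third
   standardized moment, divisor-*n*) is compared against 0.41, boundary
   inclusive; when no SQI table is supplied the index is computed from the
   raw samples and any positive value is accepted.  Pulse onsets are local
   minima with prominence at least 10% of the record range that are
   followed within 0.35 s by a rise reaching the record's 0.75 quantile.
   The upstroke gate is the package's answer to a real failure mode:
   prominence alone cannot separate the inter-beat minimum from a deep
   dicrotic notch whenever a partial beat at a record edge lowers one
   junction's prominence, but only a true onset is followed by a systolic
   upstroke.  Onsets closer than 0.3 s (a 200 bpm ceiling) are thinned,
   deeper minima winning.  The analyzed beat is the slice between the first
   two onsets (Min1–Min2), inclusive; both can be overridden per subject,
   mirroring interactive adjustment.

4. **Fiducial detection.**  On the beat segment, with `T` the beat length
   in samples:
   * `O` = segment start, `S` = global maximum.
   * `a` = APG maximum within the systolic region (first 40% of `T`,
     capped at `S`); because the a-dome's top can be broad, the reported
     index is the midpoint of its level set 10% below the maximum — the
     dome's steep flanks localize far more sharply under noise than its
     flat top.  `b` = APG global minimum after `a`.
   * `e`/`f` are anchored on the dicrotic notch, a pulse-level feature that
     survives bandpass conditioning far better than any jerk-level count:
     the anchor is the most prominent PPG minimum between `S` and `0.92 T`
     (or the most prominent VPG maximum there when the notch is a mere
     inflection); `e` is the downward JPG zero-crossing nearest the anchor
     and `f` the first upward crossing after it.  `N = e`, `D = f`.
   * The region strictly between `b` and `e` is classified: **III** when
     the APG has a max-then-min pair with prominence ≥ 3% of the APG range;
     else **I** when the JPG has an interior minimum with prominence ≥ 4.5%
     of the JPG range; else **II**.  The jerk threshold is the higher one
     because the conditioned jerk carries residual ripple that the APG does
     not.  c/d then follow the case rules quoted above; a beat whose
     required structure is absent is flagged `cd_present = 0`, never an
     error.
   * `w`/`y` = VPG global maximum before / minimum after `S`; `x` = the
     VPG sample aligned with `S` (its zero-crossing at the apex); `z` = the
     first APG zero-crossing after `e`.
   * Indices of derivative-borne points carry a one-sample compensation
     onto the PPG grid, because a left-aligned difference estimates each
     derivative roughly half a sample late per order.

5. **Features and export.**  Per beat, 15 magnitudes (each read off the
   waveform owning the point, plus `Min2`, the filtered amplitude at the
   closing onset) and 15 times in seconds from the beat onset (`O_t = 0`).
   All exported sample indices are 1-based.  Missing c/d values are `NA`
   in memory and empty cells in CSV; numbers are written with 15
   significant digits so re-reading reproduces them.

## Conventions and numerical choices

* Derivatives are iterated first differences (the velocity at array
  position *t* is `y(t+1) − y(t)`), assigned to the left index; the
  trailing samples a *k*-th difference cannot reach are filled with the
  last validly computed value, never with an artificial zero — an
  artificial zero at the tail creates a jerk spike an order of magnitude
  above the physiologic range.
* Local extrema are strict, with plateau ties resolved to the leftmost
  sample; prominence is the classical topographic definition.
* Zero-crossings are reported at the first sample of the new sign regime;
  exact zeros belong to the following regime.
* The 2.5%·`T` offsets of Case II and all index arithmetic round half away
  from zero; displayed metrics round half away from zero to two decimals
  while machine output keeps full doubles.
* Matching tolerance for evaluation defaults to 10 ms; a mislocated point
  counts as FP + FN by default (one spurious detection plus one miss),
  with `fp_only = TRUE` to count it once.
* The Case II "second JPG minimum" is counted from the segment start with
  a 4% prominence floor, so the count cannot be derailed by ripple-scale
  wiggles.

## The synthetic generator

`beat_params()` models one beat as a sum of five Gaussian pulses: systolic
(amplitude 1, center 0.20 of the beat, width 0.08), a decay shoulder
(0.60 / 0.30 / 0.10) that makes the upstroke much steeper than the decline
— which is what pins the a and b waves to the upstroke, as in real pulses
— a late-systolic bump whose amplitude is the single knob steering the
c/d morphology, a distinct diastolic wave (0.45 / 0.62 / 0.085) forming
the dicrotic notch, and a slow runoff tail (0.35 / 0.86 / 0.08) that
feeds the inter-beat valley so consecutive beats meet in a sharp,
well-conditioned onset minimum.  The default beat lasts 1.08 s (≈56 bpm,
the slow-resting end of normal): a deliberate choice, because the 0.4–8 Hz
study filter begins to attenuate well below its 8 Hz edge and a slower
beat keeps the c/d excursion's jerk signature inside the flat band.
`case_params()` freezes three bump amplitudes (0.03 / 0.35 / 0.60, the
Case III preset slightly narrower) that place each archetype comfortably
on its side of the classification thresholds in both the continuous truth
and the conditioned discrete signal.

Ground truth is computed on the noiseless continuous model by dense
numerical search at 10× the sampling rate, applying the same geometric
definitions to the analytic derivatives — never by running the detector on
the sampled signal, so truth and detection stay independent.
`simulate_record()` lays down three beats (the record starts mid-beat so
both edges sit in quiet diastolic tails, minimizing bandpass edge
transients), adds white noise and a sinusoidal baseline drift, and reports
per-beat truths in record coordinates; noise never alters the truth.
`make_benchmark()` draws per-subject cases from the 140/54/25 proportions
and jitters beat length (1.02–1.12 s), overall amplitude (±20%) and pulse
centers (≈±1%) for between-subject realism.

What the generator does **not** emulate: motion artifacts, arrhythmic or
missed beats, respiratory amplitude modulation, sensor saturation, and
morphologies outside its Gaussian-sum family.  Passing the synthetic
benchmark therefore demonstrates correctness of the algorithmic chain
under controlled conditions — not clinical-grade performance on arbitrary
recordings.

## Open design decisions

Several operational rules had to be made precise where the underlying
procedure is usually described qualitatively:

* *Case classification thresholds.*  "Prominent" became explicit
  prominence fractions (3% APG, 4.5% JPG).  The split thresholds reflect
  the different ripple floors of the two waveforms after conditioning.
* *e/f location.*  Counting JPG zero-crossings from the b wave is fragile:
  late diastolic curvature lobes add crossings and break any fixed count.
  Anchoring on the notch — the feature e and f are defined around — is
  robust across all three cases and is exactly mirrored in the truth
  oracle.
* *Case I's d wave* is read as the APG signal's own zero-crossing inside
  (b, e).  Reading it as a JPG crossing would be degenerate: when the APG
  is monotone between b and e, the JPG has no crossing there at all.
* *x* is defined as the VPG index aligned with S, its zero-crossing at the
  systolic apex.
* *Onset boundary conventions*: threshold comparisons are inclusive
  (`Ssqi ≥ 0.41`), the beat slice is inclusive of both onsets, and the
  time origin of every `_t` feature is the beat's own onset.
* *Evaluation scale*: beats are scored per named point, never across
  names, and stratification uses the reference's case label when present.

## Problem sizes used in the validation suite

The test suite validates the pipeline on a 219-subject synthetic benchmark
at 20 dB SNR and 10 ms tolerance, on noiseless sampled beats at 3 ms
tolerance (18 beats across the three archetypes), and on property checks
over smaller seeded ensembles; `scripts/acceptance.R` re-runs the same
computations from scratch for any seed.

## Known limitations

* The detector analyzes one beat per record (the first onset-bounded
  slice), matching the single-segment-per-subject design; multi-beat
  tracking and averaging are out of scope.
* Landmarks whose defining feature is flat — a broad a-dome, a heavily
  damped notch — are localized to within a few milliseconds, not exactly:
  the 0.4–8 Hz conditioning imposes an irreducible smoothing of
  curvature-level structure, and beats near a classification boundary can
  flip between Case I and Case II under noise.
* The skewness SQI is a coarse quality gate; it cannot detect all artifact
  types (e.g. symmetric motion noise).
* Sampling rates far below 1 kHz shrink every index-based tolerance; the
  package assumes research-grade sampling.
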