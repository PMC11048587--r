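---
title: "Analysing vocal-fold vibration onset: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing vocal-fold vibration onset: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymovox)
```

## The problem

When a speaker starts voicing, the vocal folds first approach the midline
(adduction), then begin to oscillate at low amplitude, and within a handful
of glottal cycles settle into sustained, periodic vibration. How long each
stage takes, and how the pattern changes with loudness, is clinically
informative: pathologies such as muscle tension dysphonia or scarring
prolong the pre-phonation delay or the transition to steady state. High
speed laryngoscopy (around 2000 frames per second) resolves individual
glottal cycles and, combined with simultaneous aerodynamic recording
(sound pressure level, airflow, intraoral pressure), allows onset dynamics
to be related to the aerodynamic cost of producing soft, modal and loud
voice.

`kymovox` implements that analysis chain end to end:

1. **Kymography** — reduce the video to a digital kymogram (DKG): the pixel
   row at one mid-membranous scanline, stacked over time.
2. **Edge tracking** — convert the kymogram to a *vibrogram*: per frame,
   the subpixel positions of the left and right glottal edges and the
   glottal width between them.
3. **Onset metrics** — locate the adduction criterion, the just-noticeable
   oscillation onset and the start of steady state; derive pre-phonation
   time and cycles to steady state.
4. **Spectral analysis** — FFT of the vibrogram width series; peak powers
   at the fundamental and its harmonics.
5. **Aerodynamics** — segment [pa:pa:] tokens in the multichannel trace,
   estimate subglottic pressure from bilabial occlusion peaks, and derive
   glottal resistance `(pressure/flow) x 1000` and resistance change per
   dB across loudness transitions.

Because raw recordings of this kind are not publicly deposited, a
first-class synthetic-data module generates frame stacks, kymograms and
aerodynamic traces with exact ground truth, so every stage is tested by
parameter recovery rather than against unavailable videos.

## The synthetic glottis

The simulator renders the minimal geometry that exercises kymography and
edge tracking: two bright fold bands converging on a dark medial gap, with
edges rendered by pixel-area coverage so that true edge positions are
meaningful at sub-pixel resolution. Photorealism is deliberately out of
scope — acceptance is parameter recovery, not appearance.

The per-frame half-gap is

$$ g(t) = \max\{0,\; G(t) - A(t)\cos(2\pi f_0 (t - t_\mathrm{osc}))\} $$

where `G(t)` ramps linearly from the resting half-gap to the post-adduction
(phonatory posture) half-gap during adduction, and the oscillation
envelope grows as `A(t) = A_s (1 - exp(-(t - t_osc)/tau))` with
`tau = growth_tau_cycles / f0` seconds. Oscillation begins a configurable
pre-phonation delay after the ramp first reaches one third of the resting
gap.

Two structural consequences of this clipped-cosine model are worth
spelling out:

* **The closed quotient fixes the posture gap.** The cycle is closed
  (width exactly zero) while `A cos(2*pi*f0*t) >= G_final`, so the closed
  fraction is `acos(G_final/A)/pi`. For `closed_quotient` to be an exact
  dial, the post-adduction half-gap must equal
  `A_s * cos(pi * closed_quotient)`. With `closed_quotient = 0` the steady
  half-gap is a pure sinusoid about `G_final = A_s` that grazes closure
  once per cycle: onset never requires a complete approximation of the
  folds, which is the physiologically realistic regime.
* **The resting gap defaults to `3 * A_s`**, which guarantees the
  one-third adduction criterion is crossed at or before the end of the
  ramp for every closed quotient.

Defaults (2000 fps, 0.5 s, 200 Hz, 15 px steady half-amplitude, 1.5-cycle
growth constant, closed quotient 0.2, 50 ms adduction start, 100 ms ramp,
100 ms pre-phonation delay, additive intensity noise SD 2 of 255) describe
a typical modal onset at this recording geometry. Pre-phonation delays are
not quantified per loudness level anywhere we could anchor them, so the
simulator treats the delay as a free ground-truth parameter; values of
20–300 ms are used across the test suite. "Whiteout" — the loss of the
glottal view when the epiglottis retroflexes over the larynx during
strained loud onsets — is rendered as full-frame saturation over a
configurable interval.

What the simulator does **not** emulate: endoscope motion, non-uniform
illumination, specular reflections, mucosal-wave texture, or genuinely
aperiodic vibration. Passing tests therefore demonstrate correctness of
the measurement chain under controlled conditions, not robustness to every
clinical image-quality failure; the QC module exists precisely because
real grainy recordings defeat edge tracking.

## Edge tracking

Per kymogram row, the glottal gap is the below-threshold run nearest the
previous row's gap centre (first row: the image centre); ties go to the
wider, then the more medial run. The threshold defaults to the fraction
0.5 of the row's min-to-max intensity range, which makes the tracked width
invariant to global intensity gain. Edge positions are refined by linear
interpolation between the two pixels straddling the threshold.

Two numerical details:

* **Narrow gaps.** When the threshold-crossing width falls below 2.5 px,
  the dip spans only one or two pixels and threshold crossings quantise
  (a symmetric two-pixel dip always reads as 2 px, regardless of the true
  sub-pixel gap). The gap is then re-estimated from the integrated
  normalised darkness of the dip, which is exact for coverage-rendered
  edges, and the edges are re-centred on the darkness centroid. This keeps
  the worst-case noiseless width error below 0.3 px; without it, errors
  approached 1.5 px near closure.
* **Closed and untrackable rows.** A row with no below-threshold run and
  uniformly bright intensities is a closed glottis: width exactly 0,
  edges at the gap centroid of the nearest open row, `valid = TRUE`. A row
  in which at least 95% of pixels exceed 0.9 of the 8-bit full scale is
  whiteout (`valid = FALSE`); full scale, not the kymogram maximum, is the
  reference because in a recording without whiteout the closed-glottis
  rows themselves sit at the kymogram maximum. Rows below the 30-unit
  contrast floor that are not uniformly bright are untrackable.

`fill_gaps()` linearly interpolates invalid runs up to a configurable
length (flagged `imputed`); `vibrogram_qc()` reports the valid fraction,
mean row contrast and whiteout intervals, standing in for the visual
verification a clinician would perform.

## Onset landmarks

All landmark detection operates on a 3-frame running-median smoothed width
(suppresses single-frame tracking jitter without shifting landmarks by
more than a frame). Cycles are delimited valley-to-valley, each containing
one width maximum; per-cycle amplitude is the peak width minus the cycle's
starting valley width, which tracks the growth envelope directly.

* **Adduction criterion**: first frame at which the width falls to one
  third of its pre-gesture reference and stays there for at least 5 ms.
  The reference defaults to the median width of the initial quiet segment.
  The "one third of the width" criterion is interpreted on the glottal
  *gap* width (the fold width itself is never available in pixels from a
  kymogram alone); the reference used is attached to the report so the
  interpretation is auditable.
* **Oscillation onset** ("just noticeable" vibration) is operationalised
  as the first cycle whose amplitude exceeds `k = 3` standard deviations
  of the quiet-segment noise floor. The landmark is then refined backwards
  from that cycle's peak on a detrended residual (width minus a one-period
  running median): the onset is the last pair of consecutive frames whose
  residual stays within the noise floor. The refinement matters because
  the first cycle's starting valley lags the true oscillation start by
  roughly `fps/(2 pi f0)` frames — over 3 frames at 100 Hz — whereas the
  residual departs from zero immediately. Raising `k` can only move the
  onset later.
* **Steady state**: the first run of `M = 3` consecutive, contiguous
  cycles stable in period and amplitude. Periods must each lie within 10%
  of the run median (with a one-frame floor, since cycle boundaries are
  quantised). Amplitude stability is judged by the run's *total spread*
  relative to its median, not each cycle's deviation from the median: a
  monotone run drifting upward by twice the tolerance still has every
  member within tolerance of its median, so the per-cycle rule saturates
  after three cycles at any growth rate and cannot distinguish a slow loud
  onset from a fast soft one. The spread rule restores that sensitivity;
  with it, a soft token (growth constant 1.5 cycles) stabilises in about
  3 cycles and a loud token (4 cycles, longer closed phase) in about 5,
  with correspondingly larger frames-to-steady.

The simulator's ground-truth steady-state frame is computed by applying
the *identical* rule to the analytic amplitude envelope, so recovery tests
measure pipeline error, not a definition mismatch. Pre-phonation time is
`(onset - criterion)/fps`. A landmark is reported absent whenever
untrackable frames intervene between the previous landmark and it — a
whiteout spanning the onset therefore yields an onset report with absent
landmarks rather than a silently wrong number.

## Spectral analysis

The width series over a chosen segment (typically steady state onward) is
mean-detrended, Hann-windowed and zero-padded to the next power of two;
the one-sided power spectrum is scaled so that, unpadded, bin powers sum
to the windowed-signal energy. Harmonic peak powers are the maximum bin
within ±2 bins of `k * f0` (`k = 1..4`), tolerating slight F0 drift across
the segment; harmonics above Nyquist are absent. `p0` denotes the
fundamental and `p1..p3` the first three harmonics *above* it (2, 3 and 4
times `f0`) — the returned `harmonic_hz` vector records the convention
explicitly since "first three harmonics" is ambiguous between the two
indexings.

The fundamental is estimated as `fps / mean(period_frames)` over the
established (upper-half-amplitude) cycles. The mean, not the median, is
used deliberately: periods are quantised to whole frames, so at a true
period of, say, 16.8 frames the individual periods alternate 17, 17, 16,
... and the median snaps to an integer — a bias of several Hz — while the
mean telescopes to (span)/(cycle count). The estimate is cross-checked
against the dominant spectral peak and discrepancies above 10% are
flagged.

Peak powers are reported linearly (px²) and in dB relative to the
fundamental; no absolute calibration is attempted. Longer closed phases
enrich the harmonics: the ratio `r1 = p1/p0` grows monotonically with the
closed quotient, and a loud-configured token (higher amplitude, longer
closed phase) shows both a larger fundamental peak and a larger `r1` than
a soft one. These orderings — not absolute spectral values — are what the
acceptance suite asserts, because the source observations for this kind of
analysis are qualitative.

## Aerodynamics

Tokens are maximal runs with SPL at or above a floor (default 65 dB) for
at least 500 ms; labels follow the soft-modal-loud protocol order, with a
warning and mean-SPL ranking as fallback when the count does not fit the
expected sequence. Subglottic pressure is estimated by the standard
interpolation technique: during the bilabial [p] occlusions of [pa:pa:]
the intraoral pressure equilibrates with subglottic pressure, so each
vowel's driving pressure is linearly interpolated between the flanking
occlusion plateau values and the token estimate averages the interior
vowels. Glottal resistance is `(psub / flow) * 1000`, in cm H2O per litre
per second; per-transition measures (dB change, resistance change,
resistance change per dB) are computed on tokens ordered soft, modal,
loud, and repetitions are averaged before derivation.

Group summaries report sex-stratified means and sample SDs (n−1), mean
subglottic pressure per loudness level, the mean soft-to-loud SPL rise,
and a paired contrast of resistance-change-per-dB between the soft-to-modal
and modal-to-loud transitions. The paired t statistic is computed from its
closed form (`mean(d)/(sd(d)/sqrt(n))`, `df = n − 1`) and cross-checked
against `stats::t.test` in the unit tests; both one- and two-sided
p-values are reported because published summaries of such contrasts do not
always state sidedness. F0 central tendency is emitted both as mean and
median for the same reason.

Two cells of the bundled reference table are known not to reproduce under
recomputation from the printed raw columns: the modal-to-loud mean
resistance-change-per-dB recomputes to 11.13 (printed 11.15) and the
soft-to-modal SD to 2.52 (printed 2.49). The package recomputes rather
than patches; the SD of the modal-to-loud per-dB values (8.5) and all 18
resistance values reproduce to the printed precision.

## Problem sizes, tolerances and I/O

* Default simulated frames are 120 x 160 px (the geometry is
  resolution-independent; tests use 60-row frames and kymogram-direct
  generation for speed). The parameter-recovery study runs 100 seeded
  tokens of 0.7 s at 2000 fps, spanning F0 100–250 Hz, amplitudes 5–30 px
  and delays 20–300 ms.
* Recovery contracts, verified in the test suite: tracked width within
  1 px everywhere and 0.25 px for gaps of at least 4 px (noiseless);
  pre-phonation onset within 2 frames; cycles-to-steady within 1 cycle;
  F0 within one bin plus `fps/N`.
* Frame stacks are stored as lossless 8-bit multi-page TIFF with a JSON
  sidecar carrying the frame rate (TIFF has no fps field; reading without
  sidecar or override is an error, not a guess). Compressed video (MP4 /
  AVI) is out of scope for I/O in this implementation: no codec bindings
  are declared, and the analysis contract starts at the decoded frame
  stack. PAS traces are plain CSV (`time_s, f0_hz, spl_db, flow_ccps,
  pressure_cmH2O`); vibrograms are data frames trivially exportable with
  `write.csv`.
* All frame and pixel indices are 0-based and `time = frame/fps`;
  preprocessing applies gamma, then gain, then offset (clipped and
  rounded back to 8-bit), then right-angle rotation, then area-average
  resizing. Arbitrary-angle rotation is excluded: it would impose an
  interpolation model the measurement chain does not need, since the
  fold-vertical orientation is achieved with right angles.

## A worked example

```{r example}
params <- glottis_sim_params(f0_hz = 200, closed_quotient = 0.2, seed = 7)
sim <- generate_kymogram_direct(params)
vib <- track_edges(sim$kymogram)
report <- onset_report(vib)
report

spec <- compute_spectrum(vib, segment = c(report$steady_state_frame,
                                          max(vib$frame)))
extract_harmonic_peaks(spec, as.numeric(estimate_f0(vib)))

# aerodynamic summary of the bundled reference tokens
group_summary(table1_fixture())
```

## Known limitations

* The tracker assumes a single glottal gap per scanline; supraglottic
  structures (false folds, epiglottis) are handled only insofar as they
  saturate the view (whiteout detection), not tracked.
* Steady-state and onset definitions are operational choices (documented
  above, configurable, and echoed in every report); descriptive onset
  durations in the clinical literature are not standardised, so no
  absolute onset-time values are asserted anywhere.
* The synthetic PAS trace uses rectangular occlusion/vowel alternation;
  real traces show articulatory ramps. The pressure-interpolation
  estimator is insensitive to this by construction, but segmentation
  thresholds may need adjustment on real recordings.
* No motion compensation, no multi-scanline phonovibrograms, no voice
  offset analysis, no jitter/shimmer perturbation measures.
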