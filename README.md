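# kymovox

Digital kymography, voice-onset metrics and laryngeal aerodynamics for
high-speed laryngoscopy.

## What it is for

Voicing starts with vocal-fold adduction, a brief pre-phonation delay, and
a few growing glottal cycles before oscillation settles into a steady
state. High-speed laryngoscopy (~2000 fps) resolves those individual
cycles; recording it simultaneously with a phonatory-aerodynamic trace
(SPL, F0, airflow, intraoral pressure during [pa:pa:] tokens) relates
onset dynamics to the aerodynamic cost of soft, modal and loud voice.
`kymovox` is for voice scientists and laryngology researchers who want
that analysis chain as open, tested code:

- **Kymography** — `read_frames()`, `preprocess()`, `extract_kymogram()`:
  frame-stack I/O (lossless multi-page TIFF + JSON fps sidecar),
  gamma/gain/offset/rotation/area-average-resize preprocessing, and
  extraction of the digital kymogram (DKG) at a mid-membranous scanline
  (auto-selected by temporal variance or given explicitly).
- **Edge tracking** — `track_edges()`, `fill_gaps()`, `vibrogram_qc()`:
  subpixel left/right glottal edge positions per frame (the *vibrogram*),
  closed-phase handling (width exactly 0), whiteout and low-contrast
  detection, gap imputation and QC.
- **Onset metrics** — `detect_cycles()`, `onset_report()`: adduction
  criterion (gap at one third of its pre-gesture width), just-noticeable
  oscillation (3 sigma above the quiet-segment noise floor), steady state
  (3 consecutive stable cycles), pre-phonation time
  `(onset − criterion)/fps` and cycles to steady state.
- **Spectral** — `compute_spectrum()`, `estimate_f0()`,
  `extract_harmonic_peaks()`: Hann-windowed one-sided power spectrum of
  the width series; peak powers `p0..p3` at `f0, 2f0, 3f0, 4f0` and ratios
  `r1 = p1/p0`, `r2 = p2/p0`.
- **Aerodynamics** — `segment_tokens()`, `estimate_subglottic_pressure()`,
  `token_means()`, `resistance()`, `token_deltas()`, `group_summary()`:
  token segmentation, interpolated subglottic pressure from bilabial
  occlusion peaks, glottal resistance

  ```
  R = (Psub / U) x 1000        [cm H2O / (L/s)]
  ```

  per-transition dB change and resistance change per dB, sex-stratified
  summaries and the paired contrast of soft→modal vs modal→loud
  transitions (closed-form paired t, df = n − 1).
- **Synthetic data** — `generate_glottis_frames()`,
  `generate_kymogram_direct()`, `generate_pas_trace()`,
  `table1_fixture()`: seeded simulators with exact ground truth (landmark
  frames, true width series, token targets) and a bundled reference table
  of per-token measurements for six normophonic adults.

The half-gap model driving the simulator is a clipped cosine,
`g(t) = max(0, G(t) − A(t) cos(2 pi f0 (t − t_osc)))`, with a linear
adduction ramp `G(t)`, exponential amplitude growth
`A(t) = A_s (1 − exp(−(t − t_osc) f0 / tau_cycles))`, and closed quotient
`acos(G_final/A_s)/pi`. See the methods vignette
(`vignettes/voice-onset-analysis.Rmd`) for the model, the operational
landmark definitions and the numerical choices.

## Worked example

```r
library(kymovox)

params <- glottis_sim_params(f0_hz = 200, closed_quotient = 0.2, seed = 7)
sim <- generate_kymogram_direct(params)     # kymogram + ground truth
vib <- track_edges(sim$kymogram)            # vibrogram waveform
onset_report(vib)
#> <onset_report>
#>   adduction criterion frame:  283
#>   oscillation onset frame:    483
#>   steady state frame:         514
#>   pre-phonation time (ms):    100
#>   frames to steady:           31
#>   cycles to steady:           3
#>   reached steady:             TRUE
```

The detected landmarks recover the simulation truth (criterion frame 283,
onset 483, steady 513, 3 cycles): the 100 ms pre-phonation delay dialled
into the simulator is returned exactly, and oscillation stabilises after 3
cycles at 2000 fps (frames are 0-based; time = frame/fps).

```r
spec <- compute_spectrum(vib, segment = c(514, max(vib$frame)))
extract_harmonic_peaks(spec, as.numeric(estimate_f0(vib)))
#> <harmonic_peaks> f0 = 200.0 Hz
#>   f0    4.546e+04 px^2  (+0.0 dB re f0)
#>   2f0       51.57 px^2  (-29.5 dB re f0)
#>   3f0        68.1 px^2  (-28.2 dB re f0)
#>   4f0        79.2 px^2  (-27.6 dB re f0)

group_summary(table1_fixture())
#> <group_summary> 6 subjects
#>   psub by level (cm H2O):  soft 3.9, modal 5.7, loud 9.7
#>   mean soft->loud SPL rise: 15.3 dB
#>      sex n_tokens f0_mean f0_sd f0_median flow_mean flow_sd psub_mean psub_sd
#> 1 female        9     189  24.0       186       107    24.5      8.01    3.61
#> 2   male        9     119  12.7       121       142    52.4      4.89    2.09
#>   per-dB contrast (modal->loud vs soft->modal): t = 3.835, df = 5, p(two-sided) = 0.0122
```

Subglottic pressure rises steadily from soft (3.9 cm H2O) through modal
(5.7) to loud (9.7) phonation, and the resistance increase per decibel is
significantly larger for the modal→loud step than for soft→modal — loud
voice is aerodynamically disproportionate, not a linear extension of
getting louder.

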