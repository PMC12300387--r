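---
title: "Demodulating arterial pulse waveforms from low-finesse Fabry–Perot interferograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demodulating arterial pulse waveforms from low-finesse Fabry–Perot interferograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(fpiapw)
```

## The measurement model

In arterial applanation tonometry with a low-finesse Fabry–Perot sensor, an
elastic membrane pressed against a superficial artery forms one mirror of a
two-beam cavity. The reflected intensity is

$$I(t) = I_1 + I_2 + 2\sqrt{I_1 I_2}\,
\cos\!\Big(\frac{4\pi n}{\lambda}\big(z \pm \Delta z(t)\big) + \pi\Big),$$

with $I_1$ the fiber-end reflection, $I_2$ the membrane reflection (treated
as constant: in the low-finesse regime its variation only perturbs the
fringe amplitude slightly), $n$ the refractive index inside the cavity,
$\lambda$ the source wavelength, $z$ the static cavity length and
$\Delta z(t)$ the pulse-driven displacement. The phase changes by $\pi$
whenever $\Delta z$ changes by the *halfwave quantum*

$$q = \frac{\lambda}{4n} \approx 386.7\ \mathrm{nm}
\quad(\lambda = 1551.3\ \mathrm{nm},\ n = 1.003),$$

so successive intensity extrema mark successive quanta of membrane travel.
That quantum is simultaneously the method's displacement resolution:
between fringe anchors the curve is interpolation, not measurement.

Because the arterial pulse amplitude (15–20 µm, i.e. 40–50 quanta) far
exceeds $\lambda/4$ and no quadrature second channel exists, the direction
of phase progression is ambiguous at every reversal of membrane motion.
The pipeline resolves this with the physiology of the waveform itself: a
cardiac cycle contains a small, even number of reversals — start of
systole, systolic peak, dicrotic notch, dicrotic-wave peak — called
*breakpoints* (BP). Between breakpoints the halfwave number $m$ counts
monotonically; at each breakpoint its direction flips; displacement at the
fringe anchors is $\Delta z = m\,q$.

## Pipeline stages and the parameters that matter

### Preprocessing

* **Outlier repair** (`zscore_threshold`, default 3.0): samples beyond the
  threshold on the global z-score are replaced by linear interpolation
  between valid neighbours, nearest-value fill at the edges. Global (not
  windowed) statistics match the single-pass description of the stage.
* **Drift removal** (`highpass_cutoff_hz` 0.5 Hz, order 4): Butterworth,
  applied forward–backward. Zero-phase application is non-negotiable here:
  the downstream claim is millisecond-level feature timing, and a causal
  IIR pass would add frequency-dependent delay. The effective magnitude
  response is the square of the single-pass response. Edge transients are
  controlled with odd-symmetric signal extension plus steady-state initial
  conditions, so a constant input maps to zero (not to a long transient).
* **Normalization** (`segment_length_s` 1.0): per-segment min–max to
  $[0,1]$, half-open segments $[kL,(k+1)L)$ indexed from the first sample.
  A constant segment maps to 0.5 — any value is defensible; 0.5 keeps the
  degenerate case centered. Per-segment scaling makes fringe rails
  (the 0/1 levels) locally meaningful even under slow gain drift, which
  the annotation stage exploits.

### Envelope features

The rate of change of the processed signal (central differences) is turned
into an instantaneous-amplitude envelope via the analytic signal (FFT
construction). For a frequency-modulated fringe signal this envelope tracks
$|\mathrm{d}\Delta z/\mathrm{d}t|$: maximal in the systolic upstroke,
dipping towards zero at every reversal. Differencing amplifies wide-band
noise proportionally to frequency, so a gentle zero-phase low-pass at a
tenth of the sampling rate (far above the fringe band, which tops out
around 300 Hz at the default simulation settings) precedes the gradient.

Envelope peaks (height ≥ 0.3 normalized, separation ≥ 0.5 s — capping
detection at 120 bpm) mark one event per cycle and anchor epoch averaging
over a $(-0.2, +1.0)$ s window; the normal-approximation 95% band
($\bar x \pm 1.96\,s/\sqrt{k}$) accompanies the mean. Minima of the
epoch-averaged envelope are candidate reversals; they are pruned by dip
prominence (default 0.02 against the adjacent maxima of the mean signal)
because low-rate-of-change diastolic stretches carry shallow wiggles that
are not reversals — the automatic counterpart of discarding spurious
first/last minima by hand. Each surviving epoch-relative minimum maps to
`peak_time + t_rel` for every detected peak, is pooled, de-duplicated, and
written as the minima catalog.

### Annotation

Fringe extrema are detected on the processed trace with a single-pass
hysteresis rule (`prominence`, default 0.05 normalized units): same-type
neighbours merge keeping the more extreme, and opposite-type candidates
must differ by the threshold, so the output strictly alternates MAX/MIN.

Breakpoints are constrained to detected extrema: a reversal interrupts the
cosine mid-flight, so it *is* a local extremum of $I(t)$ — but at whatever
intermediate value the cosine had reached, while ordinary fringe extrema
sit on the 0/1 rails. The default proposal rule exploits exactly this
signature: within `search_radius_s` (0.15 s) of each catalog minimum,
prefer the nearest clearly mid-scale ("partial-fringe") extremum, with two
refinements decided during design:

* the mid-scale preference applies only within half the search radius —
  neighbouring reversals are ≥ ~0.1 s apart, so a mid-scale extremum much
  farther than the estimate's own uncertainty belongs to a different
  event;
* if no candidate is mid-scale (the reversal happened to coincide with a
  fringe rail and merged with its neighbouring crossing), fall back to the
  nearest extremum; the temporal cost is bounded by the local fringe
  spacing.

A parity repair then enforces the even-breakpoints-per-cycle rule (cycles
bounded by envelope peak times): an odd cycle either promotes its most
mid-scale unlabeled extremum to BP or, lacking one, demotes its least
mid-scale BP. Manual intervention is replaced by a scriptable edit API
(add / remove / relabel / move commands from JSON or CSV, with an audit
log), so every curation step is reproducible.

### Demodulation

$m$ starts at 1 at the first extremum after the first breakpoint (start of
systole), increments by one per extremum, and flips direction at every
breakpoint. Two rule edge cases were settled as follows:

* a descending branch that recrosses the lowest fringe level just before a
  cycle-boundary reversal legitimately touches $m = 0$; $m = 0$ is
  therefore allowed **only** when the immediately following labeled point
  is a breakpoint, and any other zero — and every negative value — aborts
  with an "inconsistent annotation" error rather than clamping, because it
  means a breakpoint was missed or invented;
* the counting rule intrinsically offsets descending branches by one
  quantum relative to ascending ones (the first extremum after a peak
  re-crosses the *same* level it left). This is a bounded, known artifact:
  it is why the round-trip tolerances are one quantum RMSE and two quanta
  maximum.

A natural cubic spline through the extremum anchors supplies $\Delta z$ at
the breakpoint times — its momentum across a reversal lands between the
two quantized levels, close to the true turning value. The final curve is
a shape-preserving monotone cubic interpolant through anchors plus
breakpoints: in sparse low-velocity stretches (late diastole) anchor gaps
reach hundreds of milliseconds and a $C^2$ spline's momentum overshoots by
several quanta, whereas the monotone cubic interpolates every knot without
oscillating. No extrapolation beyond the anchored span. The per-sample `m`
column carries the last anchor's halfwave number; `delta_z` carries the
interpolant; `I2_t` the processed intensity.

Feature timing is read from the knot sequence, not from the interpolated
curve's argmax: the knot at a local maximum *is* the breakpoint observed at
the reversal itself (exact up to one sample), while the spline's maximum
between knots inherits a systematic shift from the descending-branch
quantum offset.

### Evaluation

`compute_snr()` implements $\mathrm{SNR(dB)} = 20\log_{10}(A_s/A_n)$ on RMS
amplitudes; for reconstructions the split is an 8 Hz zero-phase low-pass
(signal) versus its residual (noise) — the formula is standard, the
decomposition is this package's choice. `temporal_error()` matches truth
and detected events greedily by increasing time difference within 50 ms.
`roundtrip_validate()` chains everything on a synthetic recording with no
manual edits.

## The synthetic generator

`apw_template()` encodes one cardiac cycle as a gamma-variate systolic wave
(peaking at `systolic_fraction`, default 0.15 of the cycle), a Gaussian
dicrotic wave whose relative amplitude is controlled by
`dicrotic_notch_depth` (default 0.35; 0 removes the notch), and an
exponentially decaying diastolic baseline (`diastolic_decay_rate`, default
3 per cycle) that keeps a strictly negative slope into the cycle boundary —
the end-diastolic foot is then a crisp, well-defined reversal rather than a
flat stretch. A linear correction pins each cycle to exactly zero at both
boundaries; the composite is rescaled so the maximum equals
`peak_amplitude_um` (default 17.5 µm at 1 Hz, matching physiological
radial-artery recordings of 15–20 µm at ~1 Hz). Optional Gaussian jitter
perturbs individual cycle lengths. Default sampling is 10 kHz — about 40
samples per fringe at the fastest systolic slew — and the renderer refuses
sampling rates that would put the expected peak fringe rate above Nyquist.

What the generator deliberately does *not* emulate: motion artifacts and
contact-pressure drift, membrane mechanics, $I_2(t)$ variation, ECG
channels, and non-Gaussian noise. Passing tests on these simulations
therefore demonstrate the correctness of the demodulation logic under the
stated signal model, not robustness to every clinical artifact.

## Problem sizes and reproducibility

The validation studies run 12 cardiac cycles at 10 kHz (120 000 samples)
per seed, five seeds, at a white-noise level of 1% of the fringe amplitude
— sizes chosen so the full study completes in seconds while still pooling
over 50 systolic events. Every stochastic step takes an explicit integer
seed and restores the caller's RNG state, so identical inputs give
bit-identical recordings and artifacts (the pipeline manifest hashes make
this checkable).

## Known limitations

* The absolute sign of $\Delta z$ is unrecoverable from one wavelength;
  both physical signs demodulate to the same magnitude-from-baseline curve
  (this is asserted in the test suite, documenting rather than hiding the
  ambiguity).
* Resolution is one halfwave quantum; sub-quantum diastolic motion (the
  last ~0.4 µm of decay) is interpolated.
* At noise several times the design operating point (≳5% of fringe
  amplitude), surviving noise extrema on slow cosine flanks can masquerade
  as partial fringes; the halfwave counter then detects the inconsistency
  and aborts rather than producing a silently corrupted waveform. The edit
  API is the recovery path.
* Strong cycle jitter (≳5% of the period) blurs the epoch-averaged
  envelope, degrading the automatic catalog; epochless per-cycle detection
  would be the natural extension.
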