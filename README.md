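# fpiapw

Extraction of arterial pulse waveforms (APW) from time-domain recordings of
a low-finesse Fabry–Perot interferometer (FPI) used in arterial applanation
tonometry.

## The problem

An FPI pulse sensor does not measure arterial displacement directly. The
cavity between a cleaved fiber end and an elastic membrane pressed on the
artery reflects light with intensity

    I(t) = I1 + I2 + 2·sqrt(I1·I2) · cos( 4πn/λ · (z ± Δz(t)) + π )

where `λ` is the laser wavelength (1551.3 nm), `n` the refractive index of
the cavity medium (1.003), `z` the static cavity length and `Δz(t)` the
membrane displacement driven by the arterial pulse. Each time `Δz` changes
by one *halfwave quantum* `λ/(4n) ≈ 386.7 nm`, the intensity moves from one
extremum to the next. Recovering `Δz(t)` therefore means counting
interference fringes — and correctly handling the *breakpoints* where the
membrane reverses direction (start of systole, systolic peak, dicrotic
notch, end of diastole), because there the phase progression flips sign.

`fpiapw` implements the complete demodulation pipeline:

1. **preprocess** — input validation, z-score outlier repair, zero-phase
   4th-order Butterworth high-pass (0.5 Hz), segment-wise min–max
   normalization to [0, 1];
2. **envelope** — discrete gradient of the processed signal, Hilbert
   (analytic-signal) envelope, band-pass smoothing, envelope peak detection
   (one peak per cardiac cycle), epoch averaging with a 95% confidence band,
   and inverted peak detection that maps envelope minima — candidate phase
   reversals — back to absolute times;
3. **annotate** — fringe extremum detection with alternation repair,
   breakpoint proposal constrained to detected extrema, an even-breakpoints-
   per-cycle parity repair, a scriptable (reproducible) edit API, and
   validation of the physiological ordering rules;
4. **demodulate** — halfwave-number assignment (`m` starts at 1 after the
   first breakpoint, counts up, flips at every breakpoint), anchor
   displacements `Δz = m·λ/(4n)`, and cubic-spline reconstruction of the
   smooth displacement curve;
5. **evaluate** — SNR (`20·log10(A_signal/A_noise)` on RMS amplitudes) and
   feature-timing error against known ground truth.

A forward model (`make_apw()`, `render_interferogram()`) synthesizes
physiologically shaped APW displacement profiles (~1 Hz, 15–20 µm peaks,
systolic upstroke / dicrotic notch / diastolic decay) and renders them
through the interference law with white noise, providing ground truth for
end-to-end validation.

## Worked example

```r
library(fpiapw)

# one number that characterizes the sensor's displacement resolution
halfwave_quantum(optical_config())
#> [1] 386.665

# simulate 12 cardiac cycles, render, demodulate, score — no manual edits
run <- roundtrip_validate(apw_template(n_cycles = 12), noise_sd = 0.01, seed = 1)
run
#> <roundtrip_report>
#>   <timing_report> 11 matched pairs, mean |err| 0.3703 ms, max 0.6263 ms, unmatched truth/detected 0/0
#>   <snr_report> 37.45 dB (signal RMS 5100, noise RMS 68.44)

max(run$displacement$delta_z_nm) / 1000   # reconstructed peak, µm
#> [1] 17.51846
```

The timing report says every simulated systolic peak was recovered with a
mean absolute timing error of 0.37 ms (the method's design target is
< 3 ms); the reconstruction reaches the simulated 17.5 µm amplitude within
a fraction of one halfwave quantum.

The file-based pipeline produces the same artifacts the field scripts use
(`preprocessed.csv`, `minima.csv`, `annotations.csv`, `displacement.csv`
plus an MD5 manifest):

```r
cfg <- pipeline_config(out_dir = "out",
                       simulate = list(n_cycles = 10, noise_sd = 0.01),
                       seed = 1)
run_pipeline(cfg)
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/fpiapw.R simulate --cycles 10 --noise-sd 0.01 --seed 1 --out sim.csv
Rscript inst/cli/fpiapw.R preprocess --in sim.csv --out preprocessed.csv
Rscript inst/cli/fpiapw.R envelope   --in preprocessed.csv --out minima.csv
Rscript inst/cli/fpiapw.R annotate   --in preprocessed.csv --minima minima.csv --out annotations.csv
Rscript inst/cli/fpiapw.R demodulate --preprocessed preprocessed.csv \
                                     --annotations annotations.csv --out displacement.csv
```

## Limitations

- A single-wavelength interferogram cannot resolve the absolute direction
  of membrane motion; displacement is reported as magnitude from the
  diastolic baseline, and the reconstruction is identical for both physical
  signs of the cavity-length change.
- Displacement between fringe anchors is interpolation: resolution is one
  halfwave quantum (≈386.7 nm).
- Heavy cycle-to-cycle jitter or noise well above a few percent of the
  fringe amplitude degrades the automatic breakpoint catalog; the scripted
  edit API (`apply_edits()`) is the recovery path, mirroring manual
  curation.
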